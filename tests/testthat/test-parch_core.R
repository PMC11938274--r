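test_that("the envelope is the running minimum and is idempotent", {
  expect_equal(monotone_envelope(c(5, 4, 4, 3)), c(5, 4, 4, 3))
  expect_equal(monotone_envelope(c(5, 6, 4, 5, 3)), c(5, 5, 4, 4, 3))
  expect_error(monotone_envelope(numeric(0)), "Empty")
  set.seed(201)
  for (i in 1:1000) {
    w <- sample(0:20, sample(2:40, 1), replace = TRUE)
    eta <- monotone_envelope(w)
    expect_identical(as.numeric(eta), oracle_prefix_min(w))
    expect_identical(monotone_envelope(eta), eta) # idempotence
    expect_true(all(eta <= w) && eta[1] == w[1] && all(diff(eta) <= 0))
  }
})

test_that("autocorrelation handles the retention and no-water limits", {
  const <- autocorrelation(c(3, 3, 3, 3))
  expect_equal(as.numeric(const), rep(1, 4))
  zero <- autocorrelation(c(0, 0, 0))
  expect_equal(as.numeric(zero), rep(0, 3))
  expect_true(attr(zero, "degenerate"))
  expect_equal(as.numeric(autocorrelation(c(2, 1))), c(1, 0.8))
  expect_error(autocorrelation(numeric(0)), "Empty")
  expect_error(autocorrelation(c(1, 2)), "non-increasing")
})

test_that("autocorrelation and its time average match direct summation", {
  set.seed(203)
  for (i in 1:50) {
    w <- sample(0:50, sample(3:80, 1), replace = TRUE)
    eta <- monotone_envelope(w)
    cc <- autocorrelation(eta)
    expect_equal(as.numeric(cc), oracle_autocorr(eta), tolerance = 1e-10)
    expect_equal(
      time_averaged_autocorrelation(cc),
      mean(oracle_autocorr(eta)),
      tolerance = 1e-10
    )
    # the lag-count normalization can exceed 1 at intermediate lags by up
    # to T/(T - tau); boundedness is enforced at the PARCH-value stage
    expect_true(all(cc >= 0))
    expect_equal(cc[1], 1)
  }
})

test_that("time average respects its limits", {
  expect_equal(time_averaged_autocorrelation(rep(1, 10)), 1)
  expect_equal(time_averaged_autocorrelation(rep(0, 10)), 0)
  expect_error(time_averaged_autocorrelation(numeric(0)), "Empty")
})

test_that("reference selection takes the argmax with lexicographic ties", {
  expect_identical(select_reference(c(LYS = 0.9, ALA = 0.2, GLU = 0.7)), "LYS")
  expect_identical(select_reference(c(LYS = 0.9, ARG = 0.9)), "ARG")
  expect_identical(select_reference(c(TRP = 0.1)), "TRP")
  expect_error(select_reference(numeric(0)), "No reference")
  expect_error(select_reference(c(0.1, 0.2)), "named")
})

test_that("standardization maps retention ratios onto the 0-10 scale", {
  expect_equal(parch_value(0.7, 0.7), 10)
  expect_equal(parch_value(0, 0.7), 0)
  expect_equal(parch_value(0.35, 0.7), 5)
  expect_error(parch_value(0.5, 0), "Invalid reference")
  expect_error(parch_value(-0.1, 0.5), "nonnegative")
  over <- parch_value(0.9, 0.6)
  expect_equal(as.numeric(over), 10) # clipped
  expect_equal(attr(over, "unclipped"), 15)
})

test_that("scale invariance: a constant factor on the series leaves PV unchanged", {
  set.seed(205)
  w <- monotone_envelope(sample(1:50, 30, replace = TRUE))
  for (c0 in c(0.5, 3, 100)) {
    expect_equal(
      as.numeric(autocorrelation(c0 * w)),
      as.numeric(autocorrelation(w)),
      tolerance = 1e-10
    )
  }
  counts <- tibble::tibble(
    resname = rep(c("AAA", "BBB"), each = 30),
    time_ps = rep(seq(0, 290, 10), 2),
    count = c(w, 10 * w)
  )
  prof <- parch_score(counts, reference = "AAA")
  expect_equal(prof$pv[1], prof$pv[2], tolerance = 1e-10)
})

test_that("faster water loss never raises the time-averaged autocorrelation", {
  set.seed(207)
  for (i in 1:30) {
    a <- monotone_envelope(sample(0:30, 25, replace = TRUE))
    k <- sample(2:24, 1)
    b <- a
    b[k:25] <- floor(b[k:25] * runif(1, 0.1, 0.9)) # strictly faster decay
    expect_lte(
      time_averaged_autocorrelation(autocorrelation(b)),
      time_averaged_autocorrelation(autocorrelation(a)) + 1e-12
    )
  }
})

test_that("replicate aggregation is the arithmetic mean with sd bookkeeping", {
  one <- tibble::tibble(resname = c("ALA", "LYS"), pv = c(4, 10), cbar = c(0.2, 0.5))
  same <- aggregate_replicates(list(one, one, one))
  expect_equal(same$pv, c(4, 10))
  expect_equal(same$pv_sd, c(0, 0))
  expect_equal(same$n_replicates, c(3L, 3L))

  reps <- lapply(c(4, 5, 6), function(v) {
    tibble::tibble(resname = "ALA", pv = v, cbar = 0.1)
  })
  expect_equal(aggregate_replicates(reps)$pv, 5)

  set.seed(209)
  rnd <- lapply(1:4, function(i) {
    tibble::tibble(resname = c("AAA", "BBB"), pv = runif(2, 0, 10), cbar = 0.1)
  })
  got <- aggregate_replicates(rnd)
  mat <- sapply(rnd, function(p) p$pv)
  expect_equal(got$pv, rowMeans(mat))
  expect_equal(got$pv_sd, apply(mat, 1, sd))

  bad <- tibble::tibble(resname = "CCC", pv = 1, cbar = 0.1)
  expect_error(aggregate_replicates(list(one, bad)), "disagree")
})

test_that("full scoring pipeline is deterministic and ranks decay speed", {
  co <- generate_cohort(
    schedule = annealing_schedule(sampling_interval_ps = 50, n_replicates = 2),
    seed = 31
  )
  p1 <- parch_score(co$counts)
  p2 <- parch_score(co$counts)
  expect_identical(as.data.frame(p1), as.data.frame(p2)) # bitwise

  # instant loss scores near zero and below any slower-losing residue
  grid <- seq(0, 200, 10)
  counts <- tibble::tibble(
    resname = rep(c("FST", "SLW", "REF"), each = length(grid)),
    time_ps = rep(grid, 3),
    count = c(
      c(20, rep(0, length(grid) - 1)),
      pmax(20 - seq_along(grid) + 1, 0),
      rep(20, length(grid))
    )
  )
  prof <- parch_score(counts, reference = "REF")
  pv <- setNames(prof$pv, prof$resname)
  expect_lt(pv[["FST"]], 0.5)
  expect_lt(pv[["FST"]], pv[["SLW"]])
  expect_equal(pv[["REF"]], 10)
})

test_that("a constant-count residue matches a constant reference exactly", {
  grid <- seq(0, 100, 10)
  counts <- tibble::tibble(
    resname = rep(c("AAA", "REF"), each = length(grid)),
    time_ps = rep(grid, 2),
    count = c(rep(7, length(grid)), rep(3, length(grid)))
  )
  prof <- parch_score(counts, reference = "REF")
  expect_equal(prof$pv, c(10, 10)) # both constant: C == 1 everywhere
})

test_that("PVs stay in [0, 10] and are zero iff retention is zero", {
  set.seed(211)
  grid <- seq(0, 300, 10)
  counts <- purrr::map_dfr(1:50, function(i) {
    tibble::tibble(
      resname = sprintf("R%02d", i),
      time_ps = grid,
      count = sample(0:30, length(grid), replace = TRUE)
    )
  })
  zero <- tibble::tibble(resname = "ZZZ", time_ps = grid, count = 0L)
  prof <- parch_score(dplyr::bind_rows(counts, zero))
  expect_true(all(prof$pv >= 0 & prof$pv <= 10))
  expect_identical(prof$pv == 0, prof$cbar == 0)
  expect_equal(prof$pv[prof$resname == "ZZZ"], 0)
})

test_that("precomputed and live references agree", {
  co <- generate_cohort(
    schedule = annealing_schedule(sampling_interval_ps = 100, n_replicates = 1),
    seed = 37
  )
  live <- parch_score(co$counts)
  ref_cbar <- live$cbar[live$resname == attr(live, "reference")$resname]
  fixed <- parch_score(co$counts, reference = ref_cbar)
  expect_equal(fixed$pv, live$pv, tolerance = 1e-12)
})

test_that("tidy and glance summarize a profile", {
  co <- generate_cohort(
    schedule = annealing_schedule(sampling_interval_ps = 100, n_replicates = 2),
    seed = 41
  )
  prof <- parch_score(co$counts, model = "tip4p")
  td <- tidy(prof)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("resname", "cbar", "pv", "model") %in% names(td)))
  expect_false(inherits(td, "parch_profile"))
  gl <- glance(prof)
  expect_equal(nrow(gl), 1)
  expect_identical(gl$model, "TIP4P")
  expect_identical(gl$reference, "LYS")
  expect_equal(gl$pv_max, 10)
})
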