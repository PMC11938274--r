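test_that("box edge is twice the sum of the three radii", {
  expect_equal(box_dimension(2, 3, 3), 16)
  expect_equal(box_dimension(0, 3, 3), 12) # point solute
  expect_error(box_dimension(1, -3, 3), "d_ion")
  # monotone in each argument
  base <- box_dimension(1, 2, 3)
  expect_gt(box_dimension(1.5, 2, 3), base)
  expect_gt(box_dimension(1, 2.5, 3), base)
  expect_gt(box_dimension(1, 2, 3.5), base)
})

test_that("shell carving retains exactly the brute-force oxygen set", {
  solute <- as_parch_structure(tibble::tibble(
    chain = "A", resid = 1L, resname = "GLY", atom = "CA", element = "C",
    x = 0, y = 0, z = 0
  ))
  bulk <- generate_bulk_water(c(-1, -1, -1), c(1, 1, 1), density = 60, seed = 21)
  sys <- carve_shell(solute, bulk, d_shell = 0.415, seed = 22)
  d <- sqrt(rowSums(as.matrix(bulk)^2))
  expect_equal(nrow(sys$water_oxygens), sum(d <= 0.415 & d >= 0.24))
  # all-pairs recheck of the shell invariants
  dk <- sqrt(rowSums(as.matrix(sys$water_oxygens)^2))
  expect_true(all(dk <= 0.415 & dk >= 0.24))
})

test_that("a shell thinner than the clash cutoff retains nothing", {
  solute <- random_structure(3, spread = 0.1, seed = 5)
  bulk <- generate_bulk_water(c(-2, -2, -2), c(2, 2, 2), density = 40, seed = 6)
  sys <- carve_shell(solute, bulk, d_shell = 0.2, clash_cutoff = 0.24, seed = 7)
  expect_equal(nrow(sys$water_oxygens), 0)
})

test_that("retained count scales with shell volume around a point solute", {
  solute <- as_parch_structure(tibble::tibble(
    chain = "A", resid = 1L, resname = "GLY", atom = "CA", element = "C",
    x = 0, y = 0, z = 0
  ))
  bulk <- generate_bulk_water(c(-3, -3, -3), c(3, 3, 3), density = 200, seed = 31)
  n1 <- nrow(carve_shell(solute, bulk, d_shell = 0.6)$water_oxygens)
  n2 <- nrow(carve_shell(solute, bulk, d_shell = 1.2)$water_oxygens)
  vol <- function(r) r^3 - 0.24^3
  expect_equal(n2 / n1, vol(1.2) / vol(0.6), tolerance = 0.1)
})

test_that("carved waters follow the model's rigid geometry", {
  solute <- as_parch_structure(tibble::tibble(
    chain = "A", resid = 1L, resname = "GLY", atom = "CA", element = "C",
    x = 0, y = 0, z = 0
  ))
  bulk <- generate_bulk_water(c(-1, -1, -1), c(1, 1, 1), density = 60, seed = 41)
  sys <- carve_shell(solute, bulk, d_shell = 0.415, water_model = "TIP5P", seed = 42)
  w1 <- sys$waters[sys$waters$resid == sys$waters$resid[1], ]
  expect_setequal(w1$atom, c("OW", "HW1", "HW2", "LP1", "LP2"))
  o <- as.numeric(w1[w1$atom == "OW", c("x", "y", "z")])
  h1 <- as.numeric(w1[w1$atom == "HW1", c("x", "y", "z")])
  h2 <- as.numeric(w1[w1$atom == "HW2", c("x", "y", "z")])
  expect_equal(sqrt(sum((h1 - o)^2)), 0.09572, tolerance = 1e-9)
  cosang <- sum((h1 - o) * (h2 - o)) / (0.09572^2)
  expect_equal(acos(cosang) * 180 / pi, 104.52, tolerance = 1e-6)
})

test_that("an undersized bulk box is rejected with the required tiling", {
  solute <- random_structure(5, spread = 2, seed = 51)
  small_bulk <- generate_bulk_water(c(-0.5, -0.5, -0.5), c(0.5, 0.5, 0.5),
    density = 40, seed = 52
  )
  expect_error(carve_shell(solute, small_bulk), "too small")
  expect_error(carve_shell(solute, small_bulk, d_shell = -1), "positive")
})

make_ion_system <- function(seed = 61) {
  solute <- random_structure(20, spread = 1, seed = seed)
  bulk <- generate_bulk_water(c(-1.5, -1.5, -1.5), c(1.5, 1.5, 1.5),
    density = 35, seed = seed + 1
  )
  carve_shell(solute, bulk, seed = seed + 2)
}

test_that("counterion placement neutralizes the system at distance d_ion", {
  sys <- make_ion_system()
  out <- place_counterions(sys, net_protein_charge = 3, d_ion = 3, seed = 63)
  expect_equal(nrow(out$counterions), 3)
  expect_true(all(out$counterions$species == "CL"))
  expect_identical(system_charge(out, 3L), 0L)
  pc <- as.matrix(sys$protein$atoms[, c("x", "y", "z")])
  for (i in 1:3) {
    pos <- as.numeric(out$counterions[i, c("x", "y", "z")])
    dmin <- min(sqrt(rowSums(sweep(pc, 2, pos)^2)))
    expect_lt(abs(dmin - 3), 0.05)
  }
  # mutual separation
  ic <- as.matrix(out$counterions[, c("x", "y", "z")])
  expect_gt(min(dist(ic)), 1)
  # hydration cluster: 6 waters per ion appended
  expect_equal(nrow(out$water_oxygens), nrow(sys$water_oxygens) + 3 * 6)
})

test_that("a neutral protein gets no ions and a fixed seed reproduces placement", {
  sys <- make_ion_system(71)
  same <- place_counterions(sys, 0, seed = 72)
  expect_equal(nrow(same$counterions), 0)
  a <- place_counterions(sys, -2, seed = 73)
  b <- place_counterions(sys, -2, seed = 73)
  expect_true(all(a$counterions$species == "NA"))
  expect_identical(a$counterions, b$counterions)
  expect_identical(system_charge(a, -2L), 0L)
})

test_that("finalized box uses l = 2 (d_max + d_ion + d_b) and centers the system", {
  sys <- make_ion_system(81)
  sys <- place_counterions(sys, 1, d_ion = 3, seed = 82)
  gro <- tempfile(fileext = ".gro")
  out <- finalize_box(sys, d_b = 3, path = gro)
  expect_equal(
    out$box_edge,
    2 * (max_radius(sys$protein) + 3 + 3)
  )
  ctr <- colMeans(as.matrix(out$protein$atoms[, c("x", "y", "z")]))
  expect_equal(unname(ctr), rep(out$box_edge / 2, 3), tolerance = 1e-9)
  expect_true(file.exists(gro))
  back <- read_structure(gro)
  expect_equal(nrow(back$atoms), nrow(system_atoms(out)))
})

test_that("emitted annealing config encodes the default ramp and restraints", {
  dir <- tempfile()
  sched <- annealing_schedule() # 300 -> 800 K at 1 K / 10 ps
  s <- read_structure(write_gly_pdb())
  paths <- emit_annealing_config(sched, restraint_spec(), "TIP4P-Ew", dir,
    structure = s
  )
  kv <- parse_mdp(paths$mdp)
  temps <- as.numeric(strsplit(kv[["annealing-temp"]], " ")[[1]])
  times <- as.numeric(strsplit(kv[["annealing-time"]], " ")[[1]])
  expect_equal(temps[length(temps)], 800) # ends at 800 K
  expect_equal(diff(range(times)), 5000) # (800-300) K x 10 ps/K
  expect_equal(as.numeric(kv[["nsteps"]]), 2500000) # 5000 ps / 2 fs
  expect_equal(kv[["pcoupl"]], "no") # NVT
  # restraint include lists the 5 heavy atoms at the default constant
  posre <- readLines(paths$posre)
  expect_length(grep("^\\s*\\d+\\s+1\\s+10000", posre), 5)
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$restraint_force_constant, 1e4)
  expect_equal(manifest$water_model, "TIP4P-Ew")
})

test_that("emitted schedule round-trips through the mdp file", {
  dir <- tempfile()
  sched <- annealing_schedule(
    T_start = 310, T_end = 600, hold_ps = 5,
    time_step_fs = 0.5, sampling_interval_ps = 5
  )
  paths <- emit_annealing_config(sched, restraint_spec(), "TIP3P", dir)
  back <- read_annealing_schedule(paths$mdp)
  expect_equal(back$T_start, sched$T_start)
  expect_equal(back$T_end, sched$T_end)
  expect_equal(back$hold_ps, sched$hold_ps)
  expect_equal(back$time_step_fs, sched$time_step_fs)
  expect_equal(back$sampling_interval_ps, sched$sampling_interval_ps)
  expect_equal(back$duration_ps, sched$duration_ps)
})

test_that("schedule validation rejects inverted ramps and bad sampling", {
  expect_error(annealing_schedule(T_start = 800, T_end = 300), "exceed")
  expect_error(annealing_schedule(sampling_interval_ps = 3), "commensurate")
  expect_error(restraint_spec(force_constant = 0), "positive")
})
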