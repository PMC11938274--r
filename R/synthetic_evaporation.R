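# Seeded generator of per-residue water-count series with the statistical
# structure the scoring protocol assumes: residue-specific initial counts
# (a topography proxy), residue-specific temperature-driven water loss (a
# chemistry proxy), and transient re-adsorption blips that exercise the
# monotonicity transform. It emulates the inputs the scorer consumes; it
# makes no claim to evaporation physics.

#' Annealing schedule
#'
#' The heating protocol the counts are sampled along: solvent temperature
#' rises linearly from `T_start` to `T_end` at one kelvin per `hold_ps`
#' picoseconds (the default 1 K / 10 ps gives a 5000 ps ramp from 300 to
#' 800 K), sampled every `sampling_interval_ps`.
#'
#' @param T_start,T_end Temperatures in K; `T_end > T_start`.
#' @param hold_ps Hold time per kelvin, ps (the inverse heating rate).
#' @param time_step_fs Integrator time step for emitted configs, fs.
#' @param sampling_interval_ps Water-count sampling interval, ps; must be
#'   commensurate with `hold_ps`.
#' @param n_replicates Number of independent annealing runs.
#' @return An `annealing_schedule` list with the above fields plus
#'   `duration_ps` and the sampled `times_ps` / `temperatures_K` grids.
#' @export
#' @examples
#' sched <- annealing_schedule()
#' sched$duration_ps # 5000
annealing_schedule <- function(T_start = 300, T_end = 800, hold_ps = 10,
                               time_step_fs = 2, sampling_interval_ps = 10,
                               n_replicates = 5) {
  if (T_end <= T_start) stop("T_end must exceed T_start.", call. = FALSE)
  if (hold_ps <= 0 || sampling_interval_ps <= 0 || time_step_fs <= 0) {
    stop("hold_ps, sampling_interval_ps and time_step_fs must be positive.",
      call. = FALSE
    )
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1.", call. = FALSE)
  commensurate <- (hold_ps %% sampling_interval_ps == 0) ||
    (sampling_interval_ps %% hold_ps == 0)
  if (!commensurate) {
    stop("sampling_interval_ps must be commensurate with hold_ps.",
      call. = FALSE
    )
  }
  duration <- (T_end - T_start) * hold_ps
  times <- seq(0, duration, by = sampling_interval_ps)
  structure(
    list(
      T_start = T_start, T_end = T_end, hold_ps = hold_ps,
      rate_K_per_ps = 1 / hold_ps,
      time_step_fs = time_step_fs,
      sampling_interval_ps = sampling_interval_ps,
      n_replicates = n_replicates,
      duration_ps = duration,
      times_ps = times,
      temperatures_K = T_start + times / hold_ps
    ),
    class = "annealing_schedule"
  )
}

#' @export
print.annealing_schedule <- function(x, ...) {
  cat(
    "<annealing_schedule> ", x$T_start, " -> ", x$T_end, " K at 1 K/",
    x$hold_ps, " ps (", x$duration_ps, " ps), sampled every ",
    x$sampling_interval_ps, " ps, ", x$n_replicates, " replicate(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Generate one synthetic residue water-count series
#'
#' Each currently bound water independently survives a sampled frame at
#' temperature `T` with probability
#' `exp(-(T - T_start) / (affinity * T_scale))`: high-affinity residues
#' (the chemistry proxy) hold their water to higher temperatures. With
#' probability `p_readsorb`, one previously lost water re-binds for a
#' single frame, creating the non-monotone blips the envelope transform
#' must remove. `w0` (the topography proxy) sets how much water the
#' residue starts with.
#'
#' @param w0 Initial water count, integer `>= 0`.
#' @param affinity Retention strength, `> 0`; the count decays roughly
#'   where `T - T_start ~ affinity * T_scale`.
#' @param p_readsorb Per-frame probability of a transient re-adsorption
#'   blip, in `[0, 1]`.
#' @param schedule An [annealing_schedule()].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param T_scale Temperature scale of the survival model, K.
#' @return Tibble with `time_ps`, `temperature_K`, `count`.
#' @export
generate_series <- function(w0, affinity, p_readsorb = 0.05,
                            schedule = annealing_schedule(), seed = NULL,
                            T_scale = 100) {
  if (w0 < 0 || w0 != round(w0)) stop("w0 must be a nonnegative integer.", call. = FALSE)
  if (affinity <= 0) stop("affinity must be positive.", call. = FALSE)
  if (p_readsorb < 0 || p_readsorb > 1) {
    stop("p_readsorb must lie in [0, 1].", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  temps <- schedule$temperatures_K
  n <- length(temps)
  bound <- as.integer(w0)
  counts <- integer(n)
  counts[1] <- bound
  for (k in seq_len(n - 1L) + 1L) {
    s <- exp(-(temps[k] - schedule$T_start) / (affinity * T_scale))
    bound <- stats::rbinom(1L, bound, s)
    blip <- 0L
    if (p_readsorb > 0 && bound < w0) {
      blip <- stats::rbinom(1L, 1L, p_readsorb)
    }
    counts[k] <- bound + blip
  }
  tibble::tibble(
    time_ps = schedule$times_ps,
    temperature_K = temps,
    count = counts
  )
}

#' Default synthetic cohort: the 20 amino acids
#'
#' Residue specs emulating the calibration set: affinities span two
#' orders of magnitude (0.1 to 10), assigned along a hydrophilic-to-
#' hydrophobic ranking with lysine the strongest retainer, so the
#' reference selection exercised on this cohort mirrors the calibration
#' against the 20 zwitterionic amino acids. Initial counts vary with the
#' residue (topography proxy) and every residue has a small re-adsorption
#' probability.
#'
#' @param p_readsorb Re-adsorption probability shared by all residues.
#' @return Tibble with `resname`, `w0`, `affinity`, `p_readsorb`.
#' @export
default_cohort_specs <- function(p_readsorb = 0.05) {
  ranking <- c(
    "LYS", "ARG", "ASP", "GLU", "HIS", "ASN", "GLN", "SER", "THR", "TYR",
    "CYS", "GLY", "ALA", "TRP", "MET", "PRO", "VAL", "PHE", "LEU", "ILE"
  )
  n <- length(ranking)
  tibble::tibble(
    resname = ranking,
    w0 = as.integer(round(30 + 20 * cos(seq(0, 2 * pi, length.out = n)))),
    affinity = 10^seq(1, -1, length.out = n), # two decades, LYS highest
    p_readsorb = p_readsorb
  )
}

#' Generate a cohort of synthetic water-count series
#'
#' Produces the tidy counts table consumed by [parch_score()] plus the
#' ground-truth spec table for parameter-recovery tests. All randomness
#' flows from a single seed; a fixed seed gives bit-identical output.
#'
#' @param specs Residue specs: a data frame with `resname`, `w0`,
#'   `affinity` and optionally `p_readsorb`; defaults to
#'   [default_cohort_specs()].
#' @param schedule An [annealing_schedule()]; its `n_replicates` sets the
#'   number of independent series per residue.
#' @param seed Integer seed.
#' @param T_scale Survival temperature scale, K.
#' @return List with `counts` (columns `resname`, `replicate`, `time_ps`,
#'   `temperature_K`, `count`) and `truth` (the spec table).
#' @export
generate_cohort <- function(specs = default_cohort_specs(),
                            schedule = annealing_schedule(), seed = 1,
                            T_scale = 100) {
  specs <- tibble::as_tibble(specs)
  if (nrow(specs) == 0L) stop("Empty spec list.", call. = FALSE)
  if (anyDuplicated(specs$resname)) {
    stop("Duplicate residue keys in specs: ",
      paste(unique(specs$resname[duplicated(specs$resname)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (!"p_readsorb" %in% names(specs)) specs$p_readsorb <- 0.05
  set.seed(as.integer(seed))
  grid <- tidyr::expand_grid(
    replicate = seq_len(schedule$n_replicates),
    resname = specs$resname
  )
  counts <- purrr::pmap_dfr(grid, function(replicate, resname) {
    sp <- specs[specs$resname == resname, ]
    ser <- generate_series(
      w0 = sp$w0, affinity = sp$affinity, p_readsorb = sp$p_readsorb,
      schedule = schedule, seed = NULL, T_scale = T_scale
    )
    ser$resname <- resname
    ser$replicate <- replicate
    ser
  })
  list(
    counts = dplyr::relocate(counts, "resname", "replicate"),
    truth = specs
  )
}

#' Write a cohort to TSV files
#'
#' @param cohort Output of [generate_cohort()].
#' @param counts_path,truth_path Output paths (truth optional).
#' @return `counts_path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, counts_path, truth_path = NULL) {
  readr::write_tsv(cohort$counts, counts_path)
  if (!is.null(truth_path)) readr::write_tsv(cohort$truth, truth_path)
  invisible(counts_path)
}
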