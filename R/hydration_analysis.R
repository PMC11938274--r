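# Per-residue hydration counting along a trajectory, and the radial
# distribution function used to locate the hydration-shell boundary that
# sets d_shell. A water "surrounds" a residue when its oxygen lies within
# d_water (inclusive) of ANY atom of the residue; virtual sites are
# ignored for all four water models so counts stay comparable across
# them.

WATER_RESNAMES <- c("SOL", "HOH", "WAT", "TIP3", "TIP4", "TIP5", "T3P", "T4P", "T5P")

#' In-memory trajectory constructor
#'
#' A trajectory is a list of coordinate frames (each an `n_atoms x 3`
#' matrix in nm, rows in topology atom order) with a strictly increasing
#' time stamp per frame.
#'
#' @param coords List of `n x 3` matrices, or an `n_frames x 3n` matrix
#'   (one row per frame, xyz-interleaved).
#' @param times_ps Numeric vector of frame times, ps.
#' @return A `parch_trajectory`.
#' @export
make_trajectory <- function(coords, times_ps) {
  if (is.matrix(coords)) {
    coords <- lapply(seq_len(nrow(coords)), function(i) {
      matrix(coords[i, ], ncol = 3L, byrow = TRUE)
    })
  }
  if (length(coords) == 0L) stop("Empty trajectory.", call. = FALSE)
  if (length(times_ps) != length(coords)) {
    stop("times_ps must have one entry per frame.", call. = FALSE)
  }
  if (any(diff(times_ps) <= 0)) {
    stop("Frame times must be strictly increasing.", call. = FALSE)
  }
  n <- nrow(coords[[1]])
  if (any(vapply(coords, nrow, integer(1)) != n)) {
    stop("All frames must have the same atom count.", call. = FALSE)
  }
  structure(
    list(coords = coords, times_ps = as.numeric(times_ps), n_atoms = n),
    class = "parch_trajectory"
  )
}

#' @export
print.parch_trajectory <- function(x, ...) {
  cat(
    "<parch_trajectory> ", length(x$coords), " frames, ", x$n_atoms,
    " atoms, t = ", min(x$times_ps), "..", max(x$times_ps), " ps\n",
    sep = ""
  )
  invisible(x)
}

#' Read a trajectory from DCD or multi-model PDB
#'
#' Supported formats are DCD (binary, read via bio3d) and multi-model
#' PDB; coordinates are converted to nm. Frame times are assigned from
#' `dt_ps` (neither format reliably stores physical times).
#'
#' @param path Trajectory file.
#' @param format `"auto"` (by extension), `"dcd"` or `"pdb"`.
#' @param dt_ps Time between stored frames, ps.
#' @param t0_ps Time of the first frame, ps.
#' @return A `parch_trajectory`.
#' @export
read_trajectory <- function(path, format = c("auto", "dcd", "pdb"),
                            dt_ps = 10, t0_ps = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("File not found: '", path, "'.", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE) / 10 # Angstrom -> nm
    coords <- xyz
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    coords <- pdb$xyz / 10
  }
  make_trajectory(
    unclass(as.matrix(coords)),
    times_ps = t0_ps + dt_ps * (seq_len(nrow(as.matrix(coords))) - 1L)
  )
}

#' Count waters surrounding one residue in one frame
#'
#' The number of water molecules whose oxygen lies within `d_water`
#' (inclusive, `<=`) of any atom of the residue. With a periodic `box`
#' the minimum-image convention is applied.
#'
#' @param residue_coords `n x 3` matrix (or `x,y,z` data frame) of the
#'   residue's atom positions, nm; must be nonempty.
#' @param water_oxygens Water oxygen positions, nm.
#' @param d_water Contact cutoff, nm (default 0.315).
#' @param box Optional periodic box edge(s), nm.
#' @return Integer count.
#' @export
count_waters_frame <- function(residue_coords, water_oxygens,
                               d_water = 0.315, box = NULL) {
  rc <- as_coord_matrix(residue_coords)
  if (nrow(rc) == 0L) stop("Residue has zero atoms.", call. = FALSE)
  if (d_water <= 0) stop("d_water must be positive.", call. = FALSE)
  if (!all(is.finite(rc))) stop("Non-finite residue coordinates.", call. = FALSE)
  hits <- neighbors_within(rc, water_oxygens, cutoff = d_water, box = box)
  length(unique(unlist(hits, use.names = FALSE)))
}

# identify water-oxygen atom rows in a topology
water_oxygen_rows <- function(atoms) {
  which(
    atoms$resname %in% WATER_RESNAMES &
      grepl("^O", atoms$atom) # OW / O / OH2; virtual sites excluded
  )
}

#' Per-residue water-count series along a trajectory
#'
#' Samples the trajectory at frames nearest the regular grid spanned by
#' `sampling_interval_ps` and counts, for every standard amino-acid
#' residue, the waters within `d_water` of any of its atoms. Water
#' molecules are located by residue name (SOL/HOH/WAT/TIP*) and their
#' oxygen atom; non-amino-acid residues are not scored.
#'
#' @param trajectory A `parch_trajectory` whose atom order matches
#'   `structure`.
#' @param structure A `parch_structure` topology.
#' @param d_water Contact cutoff, nm.
#' @param sampling_interval_ps Sampling grid spacing, ps; `NULL` keeps
#'   every frame.
#' @param box Optional periodic box edge(s), nm.
#' @return Tidy counts tibble: `chain`, `resid`, `resname`, `time_ps`,
#'   `count` — the input contract of [parch_score()].
#' @export
count_series <- function(trajectory, structure, d_water = 0.315,
                         sampling_interval_ps = NULL, box = NULL) {
  stopifnot(inherits(trajectory, "parch_trajectory"))
  atoms <- structure$atoms
  if (trajectory$n_atoms != nrow(atoms)) {
    stop(
      "Atom-count mismatch: trajectory has ", trajectory$n_atoms,
      " atoms, topology has ", nrow(atoms), ".",
      call. = FALSE
    )
  }
  ow <- water_oxygen_rows(atoms)
  res <- structure_residues(structure)
  res <- res[res$standard_aa, ]
  if (nrow(res) == 0L) stop("No amino-acid residues in topology.", call. = FALSE)
  res_rows <- lapply(seq_len(nrow(res)), function(i) {
    which(
      atoms$chain == res$chain[i] & atoms$resid == res$resid[i] &
        atoms$resname == res$resname[i]
    )
  })
  times <- trajectory$times_ps
  if (is.null(sampling_interval_ps)) {
    frame_idx <- seq_along(times)
  } else {
    grid <- seq(min(times), max(times), by = sampling_interval_ps)
    frame_idx <- vapply(grid, function(g) which.min(abs(times - g)), integer(1))
  }
  out <- lapply(frame_idx, function(fi) {
    fr <- trajectory$coords[[fi]]
    wox <- fr[ow, , drop = FALSE]
    counts <- vapply(res_rows, function(rows) {
      count_waters_frame(fr[rows, , drop = FALSE], wox,
        d_water = d_water, box = box
      )
    }, integer(1))
    tibble::tibble(
      chain = res$chain, resid = res$resid, resname = res$resname,
      time_ps = times[fi], count = counts
    )
  })
  dplyr::bind_rows(out)
}

#' Write a counts table as wide TSV
#'
#' One row per sampled time, one column per residue key
#' (`chain:resid:resname`), matching the interchange layout of the
#' counting step.
#'
#' @param counts Tidy counts from [count_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  wide <- counts |>
    dplyr::mutate(
      key = paste(.data$chain, .data$resid, .data$resname, sep = ":")
    ) |>
    dplyr::select(dplyr::any_of(c("time_ps", "replicate")), "key", "count") |>
    tidyr::pivot_wider(names_from = "key", values_from = "count")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a wide counts TSV back into tidy form
#' @param path Path written by [write_counts_tsv()].
#' @return Tidy counts tibble.
#' @export
read_counts_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide |>
    tidyr::pivot_longer(
      -dplyr::any_of(c("time_ps", "replicate")),
      names_to = "key", values_to = "count"
    ) |>
    tidyr::separate_wider_delim(
      "key", ":",
      names = c("chain", "resid", "resname")
    ) |>
    dplyr::mutate(resid = as.integer(.data$resid))
}

#' Radial distribution function between two selections
#'
#' Standard pair-distribution estimate: distances between all A-B pairs
#' (over one or many frames) are histogrammed in uniform bins and
#' normalized by the ideal-gas expectation at the B number density
#' `n_B / volume`. The locations of the first and second local minima —
#' the hydration-shell boundaries — are attached as attributes.
#'
#' @param coords_a,coords_b Coordinate matrices (nm), or lists of them
#'   (one per frame).
#' @param box Periodic box edge(s), nm; also sets the normalization
#'   volume.
#' @param r_max Histogram range, nm.
#' @param bin_width Bin width, nm.
#' @return Tibble with `r` (bin centers, nm) and `g`; attributes
#'   `first_min` and `second_min` (nm, `NA` if not found).
#' @export
compute_rdf <- function(coords_a, coords_b, box, r_max = 1.2,
                        bin_width = 0.005) {
  if (!is.list(coords_a) || is.data.frame(coords_a)) coords_a <- list(coords_a)
  if (!is.list(coords_b) || is.data.frame(coords_b)) coords_b <- list(coords_b)
  stopifnot(length(coords_a) == length(coords_b))
  box <- rep_len(as.numeric(box), 3L)
  breaks <- seq(0, r_max, by = bin_width)
  nb <- length(breaks) - 1L
  hist_counts <- numeric(nb)
  n_pairs_norm <- 0
  vol <- prod(box)
  for (f in seq_along(coords_a)) {
    a <- as_coord_matrix(coords_a[[f]])
    b <- as_coord_matrix(coords_b[[f]])
    if (nrow(a) == 0L || nrow(b) == 0L) {
      stop("Empty selection in frame ", f, ".", call. = FALSE)
    }
    for (i in seq_len(nrow(a))) {
      d <- sweep(b, 2L, a[i, ])
      d <- d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
      dist <- sqrt(rowSums(d^2))
      dist <- dist[dist > 1e-9 & dist < r_max] # drop self-pairs
      if (length(dist) > 0) {
        hist_counts <- hist_counts +
          tabulate(findInterval(dist, breaks, left.open = TRUE), nbins = nb)
      }
    }
    n_pairs_norm <- n_pairs_norm + nrow(a) * (nrow(b) / vol)
  }
  r_lo <- breaks[-length(breaks)]
  r_hi <- breaks[-1]
  shell_vol <- 4 / 3 * pi * (r_hi^3 - r_lo^3)
  g <- hist_counts / (shell_vol * n_pairs_norm)
  r_mid <- (r_lo + r_hi) / 2
  minima <- local_minima_after_peak(r_mid, g)
  out <- tibble::tibble(r = r_mid, g = g)
  attr(out, "first_min") <- minima[1]
  attr(out, "second_min") <- minima[2]
  out
}

# first two local minima of g(r) after the first maximum, on a lightly
# smoothed curve so single-bin noise does not register as a shell boundary
local_minima_after_peak <- function(r, g) {
  if (length(g) < 5L) {
    return(c(NA_real_, NA_real_))
  }
  gs <- stats::filter(g, rep(1 / 5, 5), sides = 2)
  gs[is.na(gs)] <- g[is.na(gs)]
  peak <- which.max(gs)
  mins <- c()
  i <- peak + 1L
  n <- length(gs)
  while (i < n && length(mins) < 2L) {
    if (gs[i] < gs[i - 1L] && gs[i] <= gs[i + 1L]) {
      # walk to the end of any flat bottom
      j <- i
      while (j < n && gs[j + 1L] == gs[i]) j <- j + 1L
      if (j < n && gs[j + 1L] > gs[i]) mins <- c(mins, r[i])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  c(mins, rep(NA_real_, 2L - length(mins)))[1:2]
}
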