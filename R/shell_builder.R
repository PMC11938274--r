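# Assembly of the annealing simulation system: the protein wrapped in an
# explicit water shell of thickness d_shell, hydrated counterions placed a
# fixed distance d_ion from the protein surface to neutralize the system,
# and a cubic box whose edge leaves a margin d_b beyond the ions. The
# module also emits the heating protocol as an MD-engine parameter file
# (mdp dialect), a position-restraint include, and a JSON run manifest;
# it never runs the engine itself.

#' Final cubic box edge
#'
#' The box is sized from three concentric radii measured from the protein
#' center: the protein's maximum radius `d_max`, the counterion distance
#' `d_ion`, and the ion-boundary margin `d_b`; the edge is
#' `l = 2 * (d_max + d_ion + d_b)`.
#'
#' @param d_max,d_ion,d_b Radii in nm, all positive (`d_max` may be 0 for
#'   a point solute).
#' @return Box edge `l` in nm.
#' @export
#' @examples
#' box_dimension(2, 3, 3) # 16
box_dimension <- function(d_max, d_ion, d_b) {
  if (d_max < 0 || d_ion <= 0 || d_b <= 0) {
    stop("d_max must be >= 0 and d_ion, d_b > 0.", call. = FALSE)
  }
  2 * (d_max + d_ion + d_b)
}

#' Position-restraint specification
#'
#' Harmonic restraints hold the protein (and optionally the counterions)
#' in place during annealing so only the water responds to heating. The
#' default force constant is 1e4 kJ mol^-1 nm^-2, stiff enough to keep
#' heavy-atom RMSD flat through the ramp; 1e3, 5e3 and 2e4 are the other
#' values commonly swept.
#'
#' @param force_constant kJ mol^-1 nm^-2, `> 0`.
#' @param selection `"heavy"` (non-hydrogen protein atoms) or `"all"`.
#' @param restrain_counterions Restrain placed ions too (default TRUE).
#' @return A `restraint_spec` list.
#' @export
restraint_spec <- function(force_constant = 1e4,
                           selection = c("heavy", "all"),
                           restrain_counterions = TRUE) {
  if (force_constant <= 0) stop("force_constant must be positive.", call. = FALSE)
  list(
    force_constant = force_constant,
    selection = match.arg(selection),
    restrain_counterions = isTRUE(restrain_counterions)
  )
}

#' Uniform random water-oxygen positions (bulk-box surrogate)
#'
#' Generates a synthetic stand-in for a pre-equilibrated bulk water box:
#' oxygen positions uniform at the given number density over an
#' axis-aligned box. Real equilibrated boxes have short-range structure
#' this surrogate lacks; shell carving only needs positions at roughly
#' the right density.
#'
#' @param lower,upper Numeric length-3 box corners, nm.
#' @param density Water number density, molecules/nm^3 (default 33.4,
#'   liquid water at ambient conditions).
#' @param seed Optional integer seed.
#' @return Tibble of oxygen positions `x`, `y`, `z`.
#' @export
generate_bulk_water <- function(lower, upper, density = 33.4, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  lower <- rep_len(as.numeric(lower), 3L)
  upper <- rep_len(as.numeric(upper), 3L)
  if (any(upper <= lower)) stop("upper must exceed lower.", call. = FALSE)
  vol <- prod(upper - lower)
  n <- stats::rpois(1L, density * vol)
  tibble::tibble(
    x = stats::runif(n, lower[1], upper[1]),
    y = stats::runif(n, lower[2], upper[2]),
    z = stats::runif(n, lower[3], upper[3])
  )
}

# Full interaction-site table for one water molecule: oxygen at o_pos,
# hydrogens at d_OH/theta_HOH, virtual sites per the model (M site on the
# HOH bisector for the four-site models; two lone pairs for TIP5P).
build_water_sites <- function(o_pos, params, rot = diag(3)) {
  d_oh <- params$d_OH
  half <- params$theta_HOH * pi / 180 / 2
  # local frame: bisector along +x, molecular plane = xy
  h1 <- c(d_oh * cos(half), d_oh * sin(half), 0)
  h2 <- c(d_oh * cos(half), -d_oh * sin(half), 0)
  sites <- rbind(OW = c(0, 0, 0), HW1 = h1, HW2 = h2)
  if (params$n_virtual_sites == 1L) {
    sites <- rbind(sites, MW = c(params$d_OV, 0, 0))
  } else if (params$n_virtual_sites == 2L) {
    vhalf <- params$theta_VOV * pi / 180 / 2
    lp1 <- c(-params$d_OV * cos(vhalf), 0, params$d_OV * sin(vhalf))
    lp2 <- c(-params$d_OV * cos(vhalf), 0, -params$d_OV * sin(vhalf))
    sites <- rbind(sites, LP1 = lp1, LP2 = lp2)
  }
  placed <- sweep(sites %*% t(rot), 2L, o_pos, "+")
  tibble::tibble(
    atom = rownames(sites),
    x = placed[, 1], y = placed[, 2], z = placed[, 3]
  )
}

water_atom_table <- function(oxygens, params, resid_start = 1L) {
  if (nrow(oxygens) == 0L) {
    return(tibble::tibble(
      chain = character(), resid = integer(), resname = character(),
      atom = character(), element = character(),
      x = numeric(), y = numeric(), z = numeric()
    ))
  }
  mols <- lapply(seq_len(nrow(oxygens)), function(i) {
    s <- build_water_sites(
      as.numeric(oxygens[i, c("x", "y", "z")]), params, random_rotation()
    )
    s$resid <- resid_start + i - 1L
    s
  })
  dplyr::bind_rows(mols) |>
    dplyr::mutate(
      chain = "W", resname = "SOL",
      element = dplyr::case_match(
        substr(.data$atom, 1L, 1L),
        "O" ~ "O", "H" ~ "H", .default = "X" # virtual sites: no element
      )
    ) |>
    dplyr::select("chain", "resid", "resname", "atom", "element", "x", "y", "z")
}

#' Carve an explicit water shell around a protein
#'
#' Retains exactly those bulk waters whose oxygen lies within `d_shell`
#' of at least one protein atom (hydrogens included) and at least
#' `clash_cutoff` from every protein atom, then builds full interaction-
#' site molecules with the chosen water model's rigid geometry in random
#' orientations.
#'
#' @param protein A `parch_structure`.
#' @param bulk_water Oxygen positions (tibble or matrix with `x,y,z`, nm)
#'   tiling at least the protein's bounding box padded by `d_shell`; see
#'   [generate_bulk_water()].
#' @param d_shell Shell thickness, nm, `> 0` (default 0.415, the second
#'   hydration shell located from the C-alpha/water-oxygen RDF).
#' @param water_model Model id or parameter row from [get_water_model()].
#' @param clash_cutoff Minimum allowed oxygen-protein distance, nm.
#' @param seed Optional integer seed for the water orientations.
#' @return A `shell_system` with the protein, shell waters, empty ion
#'   set, and the geometry parameters.
#' @export
carve_shell <- function(protein, bulk_water, d_shell = 0.415,
                        water_model = "TIP3P", clash_cutoff = 0.24,
                        seed = NULL) {
  if (d_shell <= 0) stop("d_shell must be positive.", call. = FALSE)
  params <- if (is.character(water_model)) get_water_model(water_model) else water_model
  ox <- tibble::as_tibble(as.data.frame(as_coord_matrix(bulk_water)))
  names(ox) <- c("x", "y", "z")
  pcoords <- as_coord_matrix(protein$atoms)
  pad <- d_shell
  lo_need <- apply(pcoords, 2L, min) - pad
  hi_need <- apply(pcoords, 2L, max) + pad
  if (nrow(ox) > 0L) {
    lo_have <- apply(as.matrix(ox), 2L, min)
    hi_have <- apply(as.matrix(ox), 2L, max)
    if (any(lo_have > lo_need) || any(hi_have < hi_need)) {
      stop(
        "Bulk water box too small: must tile [",
        paste(sprintf("%.2f", lo_need), collapse = ", "), "] to [",
        paste(sprintf("%.2f", hi_need), collapse = ", "), "] nm.",
        call. = FALSE
      )
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  dmin <- min_dist_within(ox, pcoords, cutoff = d_shell)
  keep <- ox[dmin <= d_shell & dmin >= clash_cutoff, , drop = FALSE]
  new_shell_system(
    protein = protein,
    waters = water_atom_table(keep, params),
    water_oxygens = keep,
    counterions = empty_ion_table(),
    params = list(
      d_shell = d_shell, clash_cutoff = clash_cutoff,
      water_model = params$model_id, d_ion = NA_real_, d_b = NA_real_
    ),
    box_edge = NA_real_
  )
}

empty_ion_table <- function() {
  tibble::tibble(
    species = character(), charge = integer(),
    x = numeric(), y = numeric(), z = numeric()
  )
}

new_shell_system <- function(protein, waters, water_oxygens, counterions,
                             params, box_edge) {
  structure(
    list(
      protein = protein, waters = waters, water_oxygens = water_oxygens,
      counterions = counterions, params = params, box_edge = box_edge
    ),
    class = "shell_system"
  )
}

#' @export
print.shell_system <- function(x, ...) {
  cat(
    "<shell_system> ", nrow(x$protein$atoms), " protein atoms, ",
    nrow(x$water_oxygens), " shell waters (", x$params$water_model,
    "), ", nrow(x$counterions), " counterions",
    if (!is.na(x$box_edge)) paste0(", box ", round(x$box_edge, 2), " nm"),
    "\n",
    sep = ""
  )
  invisible(x)
}

# distance from a point to the nearest protein atom
nearest_protein_dist <- function(point, pcoords) {
  sqrt(min(rowSums(sweep(pcoords, 2L, point)^2)))
}

#' Place hydrated counterions at a fixed distance from the protein
#'
#' Adds `|net_protein_charge|` monovalent ions of the neutralizing
#' species (Cl- for a positive protein, Na+ for a negative one), each at
#' `d_ion` (within `tol`) from its nearest protein atom. Placement draws
#' random directions from the protein centroid and solves for the radius
#' where the nearest-atom distance equals `d_ion`, rejecting candidates
#' closer than `min_separation` to an already placed ion. Each ion
#' carries a small octahedral-like hydration cluster of the system's
#' water model (`n_hydration` waters at `hydration_dist`), the "hydrated
#' counterion" of the setup.
#'
#' @param system A `shell_system`.
#' @param net_protein_charge Integer formal charge of the protein, e.
#' @param d_ion Ion-protein surface distance, nm (default 3); must
#'   exceed `d_shell`.
#' @param seed Optional integer seed.
#' @param n_hydration Waters per ion (default 6).
#' @param min_separation Minimum ion-ion distance, nm.
#' @param tol Allowed deviation from `d_ion`, nm.
#' @param hydration_dist Ion-water oxygen distance, nm.
#' @param max_attempts Rejection-sampling budget per ion.
#' @return The system with ions (and their waters) added; total charge
#'   `net_protein_charge + sum(ion charges)` is zero.
#' @export
place_counterions <- function(system, net_protein_charge, d_ion = 3,
                              seed = NULL, n_hydration = 6,
                              min_separation = 1, tol = 0.05,
                              hydration_dist = 0.28, max_attempts = 1000L) {
  stopifnot(inherits(system, "shell_system"))
  net <- as.integer(net_protein_charge)
  system$params$d_ion <- d_ion
  if (net == 0L) {
    return(system)
  }
  if (!is.na(system$params$d_shell) && d_ion <= system$params$d_shell) {
    stop("d_ion must exceed d_shell.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  pcoords <- as_coord_matrix(system$protein$atoms)
  centroid <- colMeans(pcoords)
  d_max <- max_radius(system$protein)
  species <- if (net > 0L) "CL" else "NA"
  charge <- if (net > 0L) -1L else 1L
  placed <- matrix(numeric(0), ncol = 3L)
  attempts <- 0L
  while (nrow(placed) < abs(net)) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(
        "Counterion placement failed: placed ", nrow(placed), " of ",
        abs(net), " ions in ", max_attempts, " attempts (d_ion = ", d_ion,
        " nm, min_separation = ", min_separation, " nm).",
        call. = FALSE
      )
    }
    u <- stats::rnorm(3L)
    u <- u / sqrt(sum(u^2))
    f <- function(s) nearest_protein_dist(centroid + s * u, pcoords) - d_ion
    upper_s <- d_max + d_ion + 1
    if (f(upper_s) < 0) upper_s <- upper_s + d_ion + d_max
    s <- stats::uniroot(f, c(0, upper_s), tol = 1e-6)$root
    pos <- centroid + s * u
    if (nrow(placed) > 0L) {
      sep <- sqrt(min(rowSums(sweep(placed, 2L, pos)^2)))
      if (sep < min_separation) next
    }
    if (abs(nearest_protein_dist(pos, pcoords) - d_ion) > tol) next
    placed <- rbind(placed, pos)
  }
  ions <- tibble::tibble(
    species = species, charge = charge,
    x = placed[, 1], y = placed[, 2], z = placed[, 3]
  )
  # octahedral-like hydration cluster around each ion
  params <- get_water_model(system$params$water_model)
  axes <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
  )
  hyd <- lapply(seq_len(nrow(ions)), function(i) {
    rot <- random_rotation()
    k <- min(n_hydration, 6L)
    pos <- sweep(axes[seq_len(k), , drop = FALSE] %*% t(rot) * hydration_dist,
      2L, as.numeric(ions[i, c("x", "y", "z")]), "+"
    )
    tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3])
  })
  hyd_ox <- dplyr::bind_rows(hyd)
  start_resid <- if (nrow(system$waters) > 0L) max(system$waters$resid) + 1L else 1L
  system$waters <- dplyr::bind_rows(
    system$waters, water_atom_table(hyd_ox, params, resid_start = start_resid)
  )
  system$water_oxygens <- dplyr::bind_rows(system$water_oxygens, hyd_ox)
  system$counterions <- dplyr::bind_rows(system$counterions, ions)
  system
}

#' Total charge of a shell system
#' @param system A `shell_system`.
#' @param net_protein_charge Protein formal charge, e.
#' @return Integer total charge (protein + ions); waters are neutral.
#' @export
system_charge <- function(system, net_protein_charge) {
  as.integer(net_protein_charge) + sum(system$counterions$charge)
}

#' Finalize the box and export the assembled system
#'
#' Computes the cubic box edge from the protein's `d_max` and the `d_ion`
#' / `d_b` margins, centers the system in the box, and optionally writes
#' a GRO coordinate file.
#'
#' @param system A `shell_system` (ions already placed).
#' @param d_b Ion-boundary margin, nm (default 3).
#' @param path Optional GRO output path.
#' @return The system with `box_edge` set (and coordinates shifted to box
#'   center).
#' @export
finalize_box <- function(system, d_b = 3, path = NULL) {
  d_ion <- system$params$d_ion
  if (is.na(d_ion)) d_ion <- 3
  l <- box_dimension(max_radius(system$protein), d_ion, d_b)
  system$params$d_b <- d_b
  system$box_edge <- l
  centroid <- colMeans(as_coord_matrix(system$protein$atoms))
  shift <- rep(l / 2, 3L) - centroid
  shift_xyz <- function(df) {
    df$x <- df$x + shift[1]; df$y <- df$y + shift[2]; df$z <- df$z + shift[3]
    df
  }
  system$protein$atoms <- shift_xyz(system$protein$atoms)
  system$waters <- shift_xyz(system$waters)
  system$water_oxygens <- shift_xyz(system$water_oxygens)
  if (nrow(system$counterions) > 0L) {
    system$counterions <- shift_xyz(system$counterions)
  }
  if (!is.null(path)) {
    write_gro(system_atoms(system), path, box_edge = l)
  }
  system
}

#' Flat atom table of a shell system (protein + waters + ions)
#' @param system A `shell_system`.
#' @return Tidy atom tibble in GRO column order.
#' @export
system_atoms <- function(system) {
  prot <- system$protein$atoms
  ions <- if (nrow(system$counterions) > 0L) {
    tibble::tibble(
      chain = "I",
      resid = seq_len(nrow(system$counterions)),
      resname = system$counterions$species,
      atom = system$counterions$species,
      element = ifelse(system$counterions$species == "CL", "Cl", "Na"),
      x = system$counterions$x, y = system$counterions$y,
      z = system$counterions$z
    )
  } else {
    NULL
  }
  dplyr::bind_rows(prot, system$waters, ions)
}

#' Emit the annealing protocol as MD-engine configuration
#'
#' Writes three text artifacts to `dir`: `annealing.mdp` (NVT ensemble,
#' the temperature ramp as a single linear annealing segment equivalent
#' to the stated per-kelvin rate, time step, output interval, restraint
#' define), `posre.itp` (position restraints for the selected atoms at
#' the spec's force constant), and `manifest.json` recording every
#' protocol parameter for reproducibility.
#'
#' @param schedule An [annealing_schedule()].
#' @param restraints A [restraint_spec()].
#' @param water_model Model id; its parameter block is embedded as
#'   comments in the mdp file.
#' @param dir Output directory (created if needed).
#' @param structure Optional `parch_structure` used to enumerate
#'   restrained atom indices; without it the include lists no indices.
#' @param extra_params Named list merged into the manifest (e.g. d_shell,
#'   d_ion, d_b, seed).
#' @return Invisible named list of the three file paths.
#' @export
emit_annealing_config <- function(schedule, restraints = restraint_spec(),
                                  water_model = "TIP3P", dir = ".",
                                  structure = NULL, extra_params = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dt_ps <- schedule$time_step_fs / 1000
  nsteps <- round(schedule$duration_ps / dt_ps)
  nstout <- round(schedule$sampling_interval_ps / dt_ps)
  mdp <- c(
    "; annealing protocol (generated by parchr)",
    paste0("; water model: ", get_water_model(water_model)$model_id),
    paste0(";   ", water_model_block(water_model)),
    "define                   = -DPOSRES",
    "integrator               = md",
    sprintf("dt                       = %g", dt_ps),
    sprintf("nsteps                   = %d", nsteps),
    sprintf("nstxout-compressed       = %d", nstout),
    "pcoupl                   = no",
    "tcoupl                   = v-rescale",
    "tc-grps                  = System",
    "tau-t                    = 1.0",
    sprintf("ref-t                    = %g", schedule$T_start),
    "annealing                = single",
    "annealing-npoints        = 2",
    sprintf("annealing-time           = 0 %g", schedule$duration_ps),
    sprintf(
      "annealing-temp           = %g %g",
      schedule$T_start, schedule$T_end
    )
  )
  mdp_path <- file.path(dir, "annealing.mdp")
  writeLines(mdp, mdp_path)

  posre_path <- file.path(dir, "posre.itp")
  idx <- integer(0)
  if (!is.null(structure)) {
    sel <- if (restraints$selection == "heavy") {
      which(structure$atoms$element != "H")
    } else {
      seq_len(nrow(structure$atoms))
    }
    idx <- sel
  }
  posre <- c(
    "[ position_restraints ]",
    ";  i funct       fcx        fcy        fcz",
    if (length(idx) > 0) {
      sprintf(
        "%6d    1 %9g %9g %9g",
        idx, restraints$force_constant, restraints$force_constant,
        restraints$force_constant
      )
    }
  )
  writeLines(posre, posre_path)

  manifest_path <- file.path(dir, "manifest.json")
  manifest <- c(
    list(
      water_model = get_water_model(water_model)$model_id,
      T_start_K = schedule$T_start, T_end_K = schedule$T_end,
      hold_ps_per_K = schedule$hold_ps,
      duration_ps = schedule$duration_ps,
      time_step_fs = schedule$time_step_fs,
      sampling_interval_ps = schedule$sampling_interval_ps,
      n_replicates = schedule$n_replicates,
      restraint_force_constant = restraints$force_constant,
      restraint_selection = restraints$selection,
      restrain_counterions = restraints$restrain_counterions
    ),
    extra_params
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(mdp = mdp_path, posre = posre_path, manifest = manifest_path))
}

#' Parse an mdp-dialect parameter file
#' @param path Path to an mdp file.
#' @return Named character vector of `key = value` settings (comments
#'   stripped).
#' @export
parse_mdp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = " = "), character(1)),
    vapply(kv, `[[`, character(1), 1L)
  )
}

#' Recover the annealing schedule from an emitted mdp file
#'
#' Round-trip companion of [emit_annealing_config()]: reads back the
#' temperature ramp, time step and output interval.
#'
#' @param path Path to an `annealing.mdp`.
#' @param n_replicates Replicate count to carry (not stored in the mdp).
#' @return An [annealing_schedule()].
#' @export
read_annealing_schedule <- function(path, n_replicates = 5) {
  kv <- parse_mdp(path)
  temps <- as.numeric(strsplit(trimws(kv[["annealing-temp"]]), "\\s+")[[1]])
  times <- as.numeric(strsplit(trimws(kv[["annealing-time"]]), "\\s+")[[1]])
  dt_ps <- as.numeric(kv[["dt"]])
  annealing_schedule(
    T_start = temps[1], T_end = temps[length(temps)],
    hold_ps = diff(range(times)) / diff(range(temps)),
    time_step_fs = dt_ps * 1000,
    sampling_interval_ps = as.numeric(kv[["nstxout-compressed"]]) * dt_ps,
    n_replicates = n_replicates
  )
}
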