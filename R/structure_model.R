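# Protein structure model and standard-format I/O. Internally everything is
# one tidy atom table in nm; PDB files (Angstrom) are converted at the
# boundary. PDB parsing/writing is delegated to bio3d; GRO (a fixed-column
# nm format) is read and written directly since no installed R package
# handles it.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' The 20 standard amino-acid three-letter codes
#' @return Character vector of 20 codes, alphabetical.
#' @export
standard_amino_acids <- function() STANDARD_AA

new_parch_structure <- function(atoms, source = NA_character_) {
  structure(
    list(atoms = atoms, source = source),
    class = "parch_structure"
  )
}

#' @export
print.parch_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat(
    "<parch_structure> ", nrow(x$atoms), " atoms, ", nrow(res), " residues (",
    sum(res$standard_aa), " standard amino acids)\n",
    sep = ""
  )
  invisible(x)
}

validate_atoms <- function(atoms) {
  needed <- c("chain", "resid", "resname", "atom", "element", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    stop("Atom table is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(atoms) == 0L) {
    stop("Structure contains zero atoms.", call. = FALSE)
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    stop("Structure contains non-finite coordinates.", call. = FALSE)
  }
  atoms
}

#' Build a structure from a tidy atom table
#'
#' @param atoms A data frame with columns `chain`, `resid` (integer residue
#'   number), `resname` (3-letter code), `atom` (atom name), `element`,
#'   and coordinates `x`, `y`, `z` in nm.
#' @param source Optional provenance string.
#' @return A `parch_structure`.
#' @export
as_parch_structure <- function(atoms, source = NA_character_) {
  atoms <- tibble::as_tibble(atoms)
  new_parch_structure(validate_atoms(atoms), source = source)
}

#' Residue table of a structure
#'
#' One row per residue in order of first appearance, with an atom count and
#' a flag for the 20 standard amino acids. Non-amino-acid residues (waters,
#' ions, ligands) are carried but excluded from hydropathy scoring.
#'
#' @param structure A `parch_structure`.
#' @return Tibble with columns `chain`, `resid`, `resname`, `n_atoms`,
#'   `standard_aa`.
#' @export
structure_residues <- function(structure) {
  structure$atoms |>
    dplyr::group_by(.data$chain, .data$resid, .data$resname) |>
    dplyr::summarise(n_atoms = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(
      paste(.data$chain, .data$resid, .data$resname),
      unique(paste(
        structure$atoms$chain, structure$atoms$resid,
        structure$atoms$resname
      ))
    )) |>
    dplyr::mutate(standard_aa = .data$resname %in% STANDARD_AA)
}

check_atom_lines <- function(lines, min_len, rectypes, path) {
  is_rec <- grepl(paste0("^(", paste(rectypes, collapse = "|"), ")"), lines)
  short <- which(is_rec & nchar(lines) < min_len)
  if (length(short) > 0) {
    stop(
      "Malformed record in '", path, "' at line ", short[1],
      ": expected at least ", min_len, " columns, got ",
      nchar(lines[short[1]]), ".",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

read_structure_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # coordinates end at column 54 in the wwPDB fixed-column layout
  check_atom_lines(lines, 54L, c("ATOM  ", "HETATM"), path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0L) stop("Empty structure: no atoms in '", path, "'.", call. = FALSE)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- substr(trimws(a$elety), 1L, 1L)
  }
  atoms <- tibble::tibble(
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resid = as.integer(a$resno),
    resname = a$resid,
    atom = trimws(a$elety),
    element = trimws(elem),
    x = a$x / 10, y = a$y / 10, z = a$z / 10 # Angstrom -> nm
  )
  as_parch_structure(atoms, source = path)
}

read_structure_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("GRO file '", path, "' is too short.", call. = FALSE)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) {
    stop("Malformed record in '", path, "' at line 2: atom count expected.",
      call. = FALSE
    )
  }
  if (natoms == 0L) stop("Empty structure: no atoms in '", path, "'.", call. = FALSE)
  if (length(lines) < 2L + natoms + 1L) {
    stop("GRO file '", path, "' truncated: expected ", natoms, " atom lines.",
      call. = FALSE
    )
  }
  body <- lines[3:(2 + natoms)]
  short <- which(nchar(body) < 44L)
  if (length(short) > 0) {
    stop(
      "Malformed record in '", path, "' at line ", short[1] + 2L,
      ": GRO atom lines need at least 44 columns.",
      call. = FALSE
    )
  }
  atom <- trimws(substr(body, 11L, 15L))
  atoms <- tibble::tibble(
    chain = "A", # GRO carries no chain identifiers
    resid = as.integer(trimws(substr(body, 1L, 5L))),
    resname = trimws(substr(body, 6L, 10L)),
    atom = atom,
    element = substr(atom, 1L, 1L),
    x = as.numeric(substr(body, 21L, 28L)),
    y = as.numeric(substr(body, 29L, 36L)),
    z = as.numeric(substr(body, 37L, 44L))
  )
  as_parch_structure(atoms, source = path)
}

#' Read a protein structure from PDB or GRO
#'
#' Coordinates are stored in nm internally (PDB Angstrom values are divided
#' by 10 at read time; GRO is already nm). Residues keep file order.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return A `parch_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("File not found: '", path, "'.", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  switch(format,
    pdb = read_structure_pdb(path),
    gro = read_structure_gro(path)
  )
}

#' Maximum protein radius
#'
#' Distance from the structure's geometric center (unweighted centroid) to
#' its farthest atom, in nm. This is the `d_max` that sizes the cubic
#' simulation box together with the ion and boundary margins.
#'
#' @param structure A `parch_structure`.
#' @return Radius in nm.
#' @export
max_radius <- function(structure) {
  coords <- as.matrix(structure$atoms[, c("x", "y", "z")])
  if (nrow(coords) == 0L) stop("Empty structure.", call. = FALSE)
  center <- colMeans(coords)
  sqrt(max(rowSums(sweep(coords, 2L, center)^2)))
}

#' Write PARCH values into the B-factor column of a PDB file
#'
#' Every atom receives its residue's PARCH value in the B-factor field
#' (`%6.2f`), the conventional channel for per-residue coloring in
#' molecular viewers. Residues absent from the profile are written with a
#' sentinel of -1.00 (distinguishable from the valid score 0) unless a
#' `fill` value is given; with `fill = NULL` a missing residue is an error.
#'
#' @param structure A `parch_structure`.
#' @param profile A data frame with residue keys (`chain`, `resid`, and
#'   optionally `resname`) and a `pv` column of PARCH values.
#' @param path Output PDB path.
#' @param fill Value for residues not in the profile; default `-1` writes
#'   the sentinel, `NULL` demands full coverage.
#' @return `path`, invisibly.
#' @export
write_bfactor_pdb <- function(structure, profile, path, fill = -1) {
  keys <- intersect(c("chain", "resid"), names(profile))
  if (!"resid" %in% keys) {
    stop("Profile must carry a 'resid' column.", call. = FALSE)
  }
  if (!"pv" %in% names(profile)) {
    stop("Profile must carry a 'pv' column.", call. = FALSE)
  }
  atoms <- dplyr::left_join(
    structure$atoms,
    dplyr::distinct(
      dplyr::select(profile, dplyr::all_of(c(keys, "pv"))),
      dplyr::across(dplyr::all_of(keys)),
      .keep_all = TRUE
    ),
    by = keys
  )
  if (anyNA(atoms$pv)) {
    miss <- dplyr::distinct(
      atoms[is.na(atoms$pv), c("chain", "resid", "resname")]
    )
    if (is.null(fill)) {
      stop(
        "No PARCH value for residue(s): ",
        paste(miss$resname, miss$resid, sep = "", collapse = ", "),
        call. = FALSE
      )
    }
    atoms$pv[is.na(atoms$pv)] <- fill
  }
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))) * 10 # nm -> A
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = atoms$resid,
    resid = atoms$resname,
    chain = atoms$chain,
    elety = atoms$atom,
    elesy = atoms$element,
    eleno = seq_len(nrow(atoms)),
    b = round(atoms$pv, 2),
    o = rep(1, nrow(atoms))
  )
  invisible(path)
}

#' Write a structure (optionally with extra molecules) as GRO
#'
#' @param atoms Tidy atom table (as in [as_parch_structure()]), nm.
#' @param path Output path.
#' @param box_edge Cubic box edge in nm written on the final line.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(atoms, path, box_edge = 0, title = "parchr system") {
  n <- nrow(atoms)
  lines <- c(
    title,
    sprintf("%5d", n),
    sprintf(
      "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
      atoms$resid %% 100000L, substr(atoms$resname, 1L, 5L),
      substr(atoms$atom, 1L, 5L), seq_len(n) %% 100000L,
      atoms$x, atoms$y, atoms$z
    ),
    sprintf("%10.5f%10.5f%10.5f", box_edge, box_edge, box_edge)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Export a PARCH profile as TSV
#'
#' Columns: `chain`, `resid`, `resname`, `cbar`, `pv`, `pv_sd`,
#' `n_replicates` (those present in the profile).
#'
#' @param profile A `parch_profile` or conforming data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  cols <- intersect(
    c("chain", "resid", "resname", "cbar", "pv", "pv_sd", "n_replicates"),
    names(profile)
  )
  readr::write_tsv(dplyr::select(profile, dplyr::all_of(cols)), path)
  invisible(path)
}

#' Read a PARCH profile TSV
#' @param path Path to a TSV written by [write_profile_tsv()].
#' @return A tibble.
#' @export
read_profile_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
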