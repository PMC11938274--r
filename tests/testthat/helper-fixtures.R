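# Fixture builders: everything is generated in code at test time.

# one glycine residue, 7 atoms, coordinates in Angstrom (PDB convention)
gly_pdb_lines <- function() {
  c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.300   2.400   0.000  1.00  0.00           O",
    "ATOM      5  HA1 GLY A   1       1.800  -0.500   0.900  1.00  0.00           H",
    "ATOM      6  HA2 GLY A   1       1.800  -0.500  -0.900  1.00  0.00           H",
    "ATOM      7  OXT GLY A   1       3.250   1.500   0.000  1.00  0.00           O",
    "END"
  )
}

write_gly_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(gly_pdb_lines(), path)
  path
}

# tripeptide with well-separated residues, useful for counting fixtures
write_tripeptide_pdb <- function(path = tempfile(fileext = ".pdb")) {
  mk <- function(serial, name, res, resno, x, y, z, elem) {
    sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, name, res, resno, x, y, z, elem
    )
  }
  lines <- c(
    mk(1, " N  ", "ALA", 1, 0, 0, 0, "N"),
    mk(2, " CA ", "ALA", 1, 1.5, 0, 0, "C"),
    mk(3, " N  ", "LYS", 2, 10, 0, 0, "N"),
    mk(4, " CA ", "LYS", 2, 11.5, 0, 0, "C"),
    mk(5, " N  ", "GLY", 3, 20, 0, 0, "N"),
    mk(6, " CA ", "GLY", 3, 21.5, 0, 0, "C"),
    "END"
  )
  writeLines(lines, path)
  path
}

random_structure <- function(n_atoms, spread = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_parch_structure(tibble::tibble(
    chain = "A",
    resid = 1L,
    resname = "GLY",
    atom = paste0("C", seq_len(n_atoms)),
    element = "C",
    x = stats::runif(n_atoms, -spread, spread),
    y = stats::runif(n_atoms, -spread, spread),
    z = stats::runif(n_atoms, -spread, spread)
  ))
}

random_points <- function(n, lo, hi) {
  matrix(stats::runif(3 * n, lo, hi), ncol = 3L,
    dimnames = list(NULL, c("x", "y", "z"))
  )
}
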