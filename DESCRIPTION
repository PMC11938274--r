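Package: parchr
Title: Per-Residue Protein Hydropathy on the PARCH Scale Across Explicit Water Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes per-residue protein hydropathy on the PARCH
    (Protocol for Assigning a Residue's Character on a Hydropathy) scale:
    0 for residues that rapidly lose (or never have) hydration water, 10
    for the strongest water retainers. Builds the annealing simulation
    system (explicit water shell, hydrated counterions, sized box) and
    emits the MD-engine configuration; counts hydration-shell waters per
    residue along a heating trajectory; applies the PARCH statistic
    (monotone envelope, non-centered autocorrelation, time average,
    reference standardization to a 0-10 scale); annotates structures with
    PARCH values in the PDB B-factor column; and compares profiles across
    the TIP3P, TIP4P, TIP4P-Ew and TIP5P water models. A seeded synthetic
    evaporation generator produces water-count series with realistic
    topography, chemistry and re-adsorption structure so the whole
    pipeline is testable without a molecular dynamics engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    bio3d,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
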