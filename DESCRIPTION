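Package: kinwire
Title: Allosteric Wiring Maps for Kinesin Motor Domains from Residue
    Co-Evolution and Double-Mutant-Cycle Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to curate protein-family multiple sequence alignments,
    compute perturbation-based statistical coupling (SCA) energies and
    protein sectors, build thresholded residue co-evolution networks and map
    them onto Calpha coordinates, and validate predicted couplings with
    double-mutant-cycle thermodynamics derived from steady-state
    Michaelis-Menten kinetics. Includes fully seeded synthetic generators
    for alignments with planted co-varying column pairs, ideal-geometry
    Calpha traces, and noisy ATPase titrations, so every pipeline stage can
    be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
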