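Package: sqecharge
Title: Split-Charge Equilibration and Electronegativity-Equalization
    Partial Atomic Charges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Empirical partial atomic charges for small molecules and
    peptides by split-charge equilibration (SQE) and its formal-charge
    (SQE+q0) and fitted-initial-charge (SQE+qp) extensions, alongside the
    classical electronegativity-equalization baselines EEM, QEq and EQeq.
    Reads multi-record V2000 SD files, assigns plain-element, highest-
    bond-order (HBO) and bonded-atoms (BA) atom types, solves each
    method's linear system for per-atom charges, and fits per-type
    parameters against reference quantum-mechanical charges with two
    guided-minimization engines (GDMIN and the subset-accelerated optGM).
    Includes quality metrics (per-molecule R-squared and RMSD, per-type
    RMSD), correlation-graph data export, a synthetic molecule generator
    with known ground-truth parameters, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineR,
    lhs,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
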