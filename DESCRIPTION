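Package: tkievolve
Title: Clonal Evolution and Drug-Switching Optimization for EGFR-Mutant
    Lung Cancer Under Sequential TKI Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic four-genotype model of EGFR-mutant non-small
    cell lung cancer evolving under first/second-generation EGFR tyrosine
    kinase inhibitors (erlotinib/gefitinib, "drug A"), the third-generation
    inhibitor osimertinib ("drug B"), and their combination ("drug C").
    Cell populations sensitive to both drugs (W), T790M-mutant (X),
    C797S-mutant (Y) and doubly resistant (Z) grow exponentially and
    acquire resistance by irreversible mutation, giving a triangular
    linear ODE system solved in closed form. The package simulates
    sequential and combination treatment schedules, locates optimal
    drug-switching days, maps the best strategy as a function of the
    initial resistant-cell composition, and runs parameter-sensitivity
    sweeps, with tidy tabular results and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
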