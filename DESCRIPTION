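Package: overturnlab
Title: Growth Kinetics, DOM Diagenesis and Community Analysis for Simulated
    Overturn Incubation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy analysis pipeline for seawater remineralization
    (transplant) incubation experiments of the kind used to probe the
    bioavailability of dissolved organic matter that accumulates in seasonally
    suboxic basins. Provides logistic growth-curve fitting with a stationary
    rule of twice the half-capacity time, specific growth rates as ln-slopes
    over the exponential window, curve-integrated bacterial growth efficiency,
    total dissolved amino acid yields and the amino-acid degradation index,
    molecular-formula indices (double-bond equivalents, modified aromaticity
    index, magnitude-weighted O/C, H/C and DBE) with van Krevelen compound
    class assignment, absolute qPCR quantification of marker genes from
    standard dilution series, amplicon (ASV) prevalence filtering, rarefaction,
    diversity and taxonomic aggregation with 16S copy-number adjustment, and a
    seeded synthetic experiment generator so the whole pipeline is testable
    without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
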