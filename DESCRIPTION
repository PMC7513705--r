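Package: provtrial
Title: Quantitative Genetics of Multi-Site Common-Garden Provenance Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for replicated common-garden (provenance) trials
    with open-pollinated half-sib families. Estimates variance components,
    narrow-sense heritability and quantitative trait differentiation (Qst) from
    pedigree-structured ('animal model') REML fits built on sparse mixed-model
    equations; fits quadratic climatic transfer functions; partitions
    genotype-by-environment interaction variance and computes Wricke's
    ecovalence from family-by-site BLUPs; derives drought-related leaf and
    xylem functional traits (SLA, LDMC, theoretical hydraulic conductivity via
    the Hagen-Poiseuille law) and relates them to source climate; clusters
    provenances by principal components of long-term climate. Includes a
    seeded synthetic-trial generator with known ground truth so every
    estimator is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
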