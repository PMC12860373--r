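Package: coformerscout
Title: AI-Assisted Inverse Design of Hydrophilic Coformer Partners
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Screens small hydrophilic molecules as supramolecular coformer
    partners for poorly soluble actives. Implements the full inverse-design
    loop: molecular descriptor computation (molecular weight, hydrogen-bond
    donor count, topological polar surface area) and hashed fragment
    encoding of SMILES strings, random-forest feature-importance ranking, a
    from-scratch back-propagation neural-network suitability classifier
    with confusion-matrix evaluation, and an elitist genetic-algorithm
    search over a constrained descriptor space or discrete candidate pool.
    Also provides a seeded synthetic-library generator with a planted
    decision rule and planted optimum for benchmarking, plus the two
    standard assay formulas used to characterise the resulting delivery
    systems: Franz-cell cumulative permeation per unit area with
    aliquot-replacement correction, and CCK-8 viability with IC10/IC50
    estimation by log-linear interpolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
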