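Package: phagepanel
Title: Receptor Typing, Discriminatory Host Panels, and Classification
    Concordance for Phage Host-Range Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning bacteriophage spot-test titers into efficiency-
    of-plating (EoP) records and receptor-requirement profiles, assigning
    lettered receptor types, selecting minimal discriminatory bacterial host
    panels with a greedy algorithm, clustering phages from mixed
    binary/quantitative phenotype tables (Gower distance, complete linkage,
    silhouette-based choice of the number of clusters) or from phylogenetic
    trees (patristic distances), and quantifying agreement between competing
    classification schemes with the Adjusted Rand Index. Includes a synthetic
    data generator with planted receptor types for end-to-end validation, and
    the published receptor-typing tables of a 13+3 phage Escherichia coli
    study as built-in worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    utils
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
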