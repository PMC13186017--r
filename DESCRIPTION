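Package: phoscoreg
Title: Phosphosite Co-Regulation Network Analysis from Phosphoproteomics Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds phosphosite-resolved co-regulation networks for a target
    protein from curated compendia of global phosphoproteomics experiments.
    Ingests long-format site observation tables, applies Class-I localization
    filtering and fold-change/significance direction calling, computes
    within-protein co-occurrence statistics and concordance ratios, identifies
    high-confidence co-regulated phosphosites on other proteins with a Fisher's
    exact test gate plus ratio and multi-study evidence filters, stratifies
    partners into functional roles (upstream kinases, co-regulated kinases,
    phosphatases, binary interactors, substrates) from flat-file annotation
    resources, and exports signed networks in GraphML/SIF formats. A synthetic
    compendium generator with planted co-regulation structure supports
    calibration and recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    rlang,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
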