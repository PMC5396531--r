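Package: connatrophy
Title: Topological Length and Atrophy of White Matter Connections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking the topological length of white matter
    connections in a structural connectome to their rate of atrophy in
    premanifest Huntington's disease. Provides consensus modular partitioning
    of group-average connectomes (repeated Louvain runs with agreement-matrix
    consensus), classification of connections into cortico-striatal,
    interhemispheric, intrahemispheric and intramodular subtypes, longitudinal
    linear mixed-effects group contrasts with per-subtype false discovery rate
    control, cross-sectional and longitudinal atrophy Z-score transforms,
    shortest weighted path lengths, and the length-atrophy rank correlation.
    A synthetic-cohort generator with planted modular structure and
    length-dependent degeneration makes the whole chain testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
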