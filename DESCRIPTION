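Package: pspnet
Title: Proteomics Signature Profiling over Pathway-Derived Subnets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns inconsistent per-patient protein detection lists into
    hit-rate signature profiles over protein complexes or pathway-derived
    subnets (PDSs), clusters patients hierarchically with multiscale-bootstrap
    AU/BP confidence values, selects class-differential features by a
    permutation t-test, ranks them with an iTRAQ-ratio scoring scheme,
    quantifies empirical false-positive behaviour by random bipartition of a
    single class, analyses pathway co-localisation of significant complexes
    and subnets, and scores ontology-term association of feature sets with a
    functional-class-scoring procedure. Includes a synthetic-data generator
    emulating two-class cohorts with highly variable detection lists so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
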