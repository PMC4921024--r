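Package: fusionscan
Title: Domain-Architecture Based Detection of Gene Fusion Events in
    Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects candidate gene fusion ('Rosetta stone') proteins from
    tabular protein-versus-domain alignment hits. Identifies domain models
    that represent entire standalone genes, consolidates redundant domain
    models into sets, selects maximum sets of non-overlapping domain
    alignments per gene, and filters candidates through eight geometric and
    promiscuity criteria. Includes scoring against curated training sets,
    cohort-level fusion-frequency statistics for functional roles and
    subsystems, metabolic-pathway adjacency analysis of fused roles, and a
    seeded synthetic-cohort generator with planted ground truth for
    end-to-end benchmarking.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
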