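Package: spermnet
Title: Topology, Controllers and Robustness of Directed Protein Interactomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles directed molecular interaction networks from pathway
    edge-list fragments (with identifier harmonization and confidence-score
    filtered enrichment), characterizes their topology (degree distributions,
    power-law fits, clustering, path-length panel), identifies their
    controllers (degree hubs, kernel-density hub subpopulations,
    shortest-path-tree bottlenecks, and the hub-bottleneck control backbone),
    simulates robustness to random failure and targeted attack, and tests
    controller essentiality against knockout-phenotype contingency tables.
    Includes seeded generators for scale-free preferential-attachment networks
    and for every other input the pipeline needs, so all stages are testable
    without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
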