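Package: netboot
Title: Bootstrap Construction and Comparison of Correlation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bootstrap resampling of numeric feature tables (for example
    microbial taxon counts or clr-transformed abundances), construction of
    thresholded signed Spearman co-occurrence networks for every replicate,
    computation of seven network statistics (edges, nodes, average degree
    centrality, transitivity, average closeness, average betweenness,
    density) with graph algorithms implemented from first principles,
    replicate-paired exact two-tailed binomial tests for comparing metrics
    between two datasets, and deterministic signed-network SVG
    visualizations. Includes a seeded synthetic-data generator with planted
    correlation blocks so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
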