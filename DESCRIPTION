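Package: dpbmm
Title: Dirichlet Process Beta Mixture Models for DNA Methylation Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-based clustering of DNA methylation beta values (bounded in
    the open unit interval) with a Dirichlet process mixture of per-locus beta
    distributions. The number of clusters is learned from the data by a
    non-conjugate "no-gaps" Gibbs sampler with Metropolis-within-Gibbs updates
    of the beta shape parameters on an unconstrained log scale, Dirichlet
    resampling of the mixing proportions, and auxiliary-variable resampling of
    the concentration parameter. Includes detection p-value probe filtering,
    variance-based locus selection, BCubed precision/recall/F evaluation of
    clusterings against known labels, and synthetic-data generators for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
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
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
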