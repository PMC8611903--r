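Package: geonull
Title: Geometric Surrogate Null Models for Spatially Embedded Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how much of a structural connectome's topology is
    explained by its spatial embedding. Given a weighted symmetric
    connectivity matrix with node coordinates, volumes and pairwise fiber
    distances, the package fits the low-order log-weight-versus-distance
    trend, builds ensembles of geometric surrogate graphs (preserving the
    node-strength sequence and the fitted weight-distance relationship) and
    strength-preserving random surrogates, and compares empirical modularity,
    hub organisation, participation, efficiency and related graph measures
    against the surrogate ensembles. Includes a synthetic benchmark
    generator with planted modules and peripheral hubs, binned
    weight-distance profiles with corrected one-sample t-tests, Tukey range
    and permutation tests, and a config-driven end-to-end analysis report.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
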