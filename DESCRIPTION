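Package: trophoweb
Title: Topology, Modularity and Species Roles in Directed Food Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative topological analysis of directed (prey -> predator)
    food webs. Builds region-specific sub-webs from a meta-web by induced
    subgraphs, computes a standard structural metric suite (linkage density,
    connectance, cannibalism, loops, path length, clustering, omnivory,
    short-weighted trophic levels), finds modules by simulated annealing,
    tests modularity against degree-preserving null networks, classifies
    species' topological roles from within-module degree z-scores and
    participation coefficients, tests module association with habitat and
    trophic level by a permutation test on discriminant separation, and maps
    station-level degree centrality on a regular grid. Includes niche-model
    and planted-module generators so the whole pipeline can be exercised on
    synthetic webs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
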