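Package: rescape
Title: Corridor-Based Landscape Genetics with Boosted Trees and Resistant Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individual-based landscape genetics on codominant
    (microsatellite) genotypes: per-locus diversity statistics, exact
    Monte-Carlo Hardy-Weinberg tests, the standardized index of association,
    rarefied allelic richness in overlapping spatial genetic neighborhoods,
    three pairwise genetic distance metrics, Mantel tests and spatial
    correlograms, buffered-transect extraction of landscape variables along
    straight lines and least-cost paths, gradient-boosted resistance models
    with leave-one-spatial-cluster-out cross-validation and forward feature
    selection, accumulated local effects curves, an iterative
    straight-line-to-least-cost-path corridor refinement loop, and
    resistant-kernel connectivity mapping. Includes a synthetic-data module
    that generates landscapes, sample locations and genotypes with known
    isolation-by-resistance structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    mgcv,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
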