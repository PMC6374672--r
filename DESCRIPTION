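Package: phyloiso
Title: Phylogenetic Isolation of a Focal Species Under Extinction Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how simulated extinctions of threatened species change
    the phylogenetic originality of a focal species. Computes evolutionary
    distinctiveness (fair proportion) scores and originality ranks on rooted
    timetrees, applies sequential IUCN-category extinction scenarios, and tests
    the focal species' rank against unconstrained and phylogenetically
    constrained (Lapointe-Garland) permutation nulls. Handles missing data by
    grafting phylogenetically unplaced species onto ultrametric trees with
    branch-length-proportional placement and by iterative random-forest
    imputation of data-deficient statuses, aggregating results over replicate
    ensembles. Includes a synthetic data generator (Yule trees, liability-
    threshold statuses with tunable phylogenetic signal, correlated traits) so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
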