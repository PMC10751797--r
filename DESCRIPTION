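Package: pathstrings
Title: Linguistics-Style Clustering of Molecular Transition Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies successful source-to-target transition pathways from
    molecular simulations (conventional MD or weighted-ensemble trajectory
    trees) into mechanistic classes. Each pathway is encoded as a text string
    of visited conformational states, repeated state patterns are optionally
    condensed, pathway pairs are scored with a length-corrected Gestalt
    (longest-common-subsequence) similarity, and the resulting distance
    matrix is clustered with Ward-linkage hierarchical agglomeration.
    Includes state discretization (rectilinear bins and points, user
    assignment hooks, and a two-stage cluster-then-classify scheme for large
    data sets), pathway extraction with stride and length filters, class
    probability/duration/network summaries, and seeded synthetic ensemble
    generators for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
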