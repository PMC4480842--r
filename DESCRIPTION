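Package: readmixr
Title: Sparse Convex Decomposition of Admixture Vectors into Reference
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers the recent biogeographic ancestry of an admixed
    individual by representing its K-component admixture vector as a
    sparse convex combination of modern reference populations. The
    decomposition minimizes the Chebyshev (maximum componentwise) error
    via linear programming, and searches over population subsets with a
    greedy constructive phase, a differential-evolution global phase with
    trigonometric mutation and age-based substitution, local refinement
    over geographically and genetically close populations, and ensemble
    averaging of stable members. Supports unconditional, conditional
    (user-supplied prior populations) and equal-weights modes, and ships
    a synthetic reference-panel and simulated-admixture generator plus
    evaluation metrics so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
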