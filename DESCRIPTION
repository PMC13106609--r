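Package: heliotol
Title: Multi-Trait Evaluation of High-Light Tolerance in Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens crop germplasm for tolerance to high-light stress from
    replicate-level trait measurements. Computes per-genotype stress-tolerance
    coefficients (stress/control trait-mean ratios), weights traits objectively
    by the entropy-weight method, scores genotypes with the TOPSIS closeness
    coefficient, classifies tolerance levels by hierarchical clustering of the
    scores, and characterises trait structure with Pearson/Mantel association
    tests, out-of-bag permutation importance from a random-forest ensemble, and
    piecewise structural equation modelling with d-separation (Fisher's C)
    goodness of fit and direct/indirect/total effect decomposition. Includes a
    calibrated synthetic-cohort generator for end-to-end testing without raw
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
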