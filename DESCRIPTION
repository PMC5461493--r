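Package: pmdecode
Title: Perceptual and Mnemonic Direction Coding in Neural Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how single neurons and pseudopopulations of
    prefrontal neurons encode a visual motion direction while it is perceived
    and while it is held in working memory, in a two-task delayed
    match-to-sample design. Implements per-neuron ROC discriminability with
    label-permutation significance and functional classification, choice
    probability, pseudopopulation decoding with a diagonal linear discriminant
    classifier (leave-one-out and 2-fold cross-validation, neuron bootstraps,
    randomized-label nulls, class-removal and regional subsets), cross-temporal
    generalization and code-stability maps, decoding-error feature-proximity
    structure, anatomical clustering tests, and a synthetic-data generator with
    ground-truth tuning parameters for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
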