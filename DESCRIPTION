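Package: babra
Title: Bioactivity-Based Read-Across for In Vivo Toxicity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Read-across prediction of binary in vivo toxicity endpoints from
    high-throughput in vitro bioactivity profiles. Chemical similarity is
    measured with an unsupervised random-forest proximity matrix (real data
    versus a marginal-resampled synthetic class), optionally enriched with
    Tanimoto structural similarity from fingerprint bit-vectors, and
    predictions are weighted k-nearest-neighbor averages of neighbor
    outcomes. Includes balanced sampling of unbalanced endpoints,
    leave-one-out evaluation with sensitivity, specificity and balanced
    accuracy, permutation significance, parameter sweeps over neighborhood
    size and similarity thresholds, trinary bioprofile neighbor comparison,
    a synthetic high-throughput-screening data generator for end-to-end
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
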