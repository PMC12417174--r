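Package: skipgru
Title: Skip-Gated Recurrent Unit Diabetes Risk Classification with
    Metaheuristic Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for clinical tabular risk classification built around a
    skip-gated recurrent unit (Skip-GRU) network trained with clip-by-norm
    gradient clipping. Includes min-max normalization and polynomial-regression
    imputation of zero-coded missing values, a random-spiral-flight marine
    predator algorithm (RSFS-MPA) wrapper feature selector, stratified k-fold
    evaluation with confusion-matrix metrics, and a synthetic tabular data
    generator with planted informative features for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
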