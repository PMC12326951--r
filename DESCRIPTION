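Package: hoofpspm
Title: Pedobarographic Statistical Parametric Mapping of Equine Fore-Foot
    Trimming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how routine farriery trimming redistributes
    pressure over the solar surface of the equine fore foot, and to relate
    those changes to external hoof-shape measurements.  One arm registers
    per-strike peak-pressure prints from a walkway pressure mat to a common
    pose, computes pixel-level two-sample t-statistic fields between the
    before- and after-trimming conditions, assigns cluster-level significance
    by permutation of condition labels, and labels significant clusters with
    solar-surface regions (frog, wall, quarters, toe, heel).  The other arm
    analyses percentage differences of eighteen external hoof measures:
    univariable screening with Bonferroni correction, correlation-based
    variable pruning, forward likelihood-ratio stepwise logistic regression
    for increased frog pressure, and model evaluation by Hosmer-Lemeshow
    calibration, AUROC and sensitivity/specificity at a probability cut-off.
    A synthetic-data module generates hoof-shaped pressure-print stacks and
    measurement cohorts with known structure so the whole pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
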