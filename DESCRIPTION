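Package: cwlearn
Title: Contrast Weighted Learning for Robust Optimal Treatment Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates optimal individualized treatment rules by contrast
    weighted learning: pairwise contrasts of clinical outcomes between
    subjects (difference, truncated difference, log ratio, win indicator)
    are aggregated into per-subject classification weights and pseudo
    treatment labels, and the rule is obtained by solving a weighted
    support vector machine with linear or Gaussian kernel.  Because the
    weights depend on outcomes only through pairwise contrasts, the
    estimated rule is robust to outliers, heavy tails, and monotone
    transformations of the outcome, and applies unchanged to ordinal
    outcomes.  The package also provides inverse-probability-weighted
    value estimation, propensity score estimation by L1-penalized
    logistic regression, outcome weighted learning and Q-learning
    baselines, simulation designs with continuous and ordinal outcomes,
    and a repeated cross-validation evaluation protocol.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
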