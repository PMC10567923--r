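Package: stresstraj
Title: Spatio-Temporal Stress-Response Trajectories and Body-Mass Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating acute-stress brain-response trajectories to a
    continuous body-mass outcome. Implements concatenation of rest-task-rest
    region-of-interest (ROI) timeseries with baseline offset matching, per-edge
    hierarchical trajectory estimation with partial pooling, assembly of
    spatio-temporal activation and connectivity feature matrices,
    confound-aware nested cross-validated elastic-net prediction with
    permutation inference, decomposition of the outcome into brain-predicted
    and residual components for biomarker attribution, normalization of
    multiplex cytokine panels, and subjective, endocrine, and cardiovascular
    stress-marker derivation. A seeded synthetic-cohort generator with
    exported ground truth makes every stage testable without access to raw
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
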