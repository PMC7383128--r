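Package: msnr
Title: Multi-Scale Network Regression for Brain Connectivity Phenotypes
Version: 0.1.0
Authors@R:
    person("MSNR", "Developers", email = "msnr@example.org", role = c("aut", "cre"))
Description: Penalized multivariate regression of a stack of subject-level
    connectivity matrices on subject covariates. Each network is decomposed
    into a shared low-rank mean matrix (nuclear-norm penalty) plus sparse
    community-level covariate effects (lasso penalty on block coefficient
    matrices), fit by block coordinate descent with closed-form updates.
    Includes cross-validated tuning with iterative grid refinement, a
    permutation test of model significance, mass-univariate edge and
    community-mean baselines with FDR correction, a synthetic-data
    generator with known ground truth, post-fit interpretability
    summaries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
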