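Package: gwalign
Title: Optimal-Transport Domain Adaptation for Multichannel fNIRS Workload Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers n-back workload labels between fNIRS recording sessions and
    subjects by aligning segment-level second-order structure with entropic
    Gromov-Wasserstein coupling (session-by-session) and fused Gromov-Wasserstein
    barycenters (subject-by-subject). Includes a synthetic multichannel fNIRS
    generator with controllable session- and subject-level domain shift, modified
    Beer-Lambert conversion, spectral channel rejection, sparse transient-artifact
    (spike/step) removal, the matrix Hellinger distance on segment covariances,
    discrete optimal-transport solvers, and evaluation utilities (confusion
    matrices, inverse-variance weighted summaries, significance tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
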