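Package: aaruda
Title: Unsupervised Domain Adaptation for Animal Activity Recognition from
    Inertial Sensor Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing animal activities (lying, sitting, standing,
    walking, trotting, sniffing, ...) from 6-axis inertial measurement unit
    recordings when the labeled training data and the deployment data come from
    different domains (sensor position, animal size, gender, or species).
    Implements a 1-D residual convolutional feature extractor with a
    fully-connected label head, and three unsupervised domain-adaptation
    objectives: multi-kernel maximum mean discrepancy matching (DAN),
    gradient-reversal adversarial training (DANN), and target-domain
    reconstruction (DRCN). Includes sliding-window segmentation of annotated
    streams, stratified five-fold cross-validation, accuracy/precision/recall/F1
    reporting, latent-space analysis (PCA + t-SNE, domain probes, neighbor
    mixing scores), and a synthetic domain-shifted IMU generator so the whole
    pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
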