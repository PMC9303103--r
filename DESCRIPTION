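Package: cwdistill
Title: Channel-Wise Knowledge Distillation for Fine-Grained Vessel
    Segmentation in Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Training and evaluation toolkit for fine-grained semantic
    segmentation of the three great vessels (pulmonary artery, aorta,
    superior vena cava) in fetal echocardiographic three-vessel views.
    A teacher network is trained on region-of-interest crops of the
    annotated vessel region and its logits, restored to full-image
    coordinates, supervise a student network trained on full-size images
    through a channel-wise knowledge-distillation loss (per-class spatial
    softmax aligned by KL divergence at a distillation temperature).
    Includes a synthetic speckle-phantom generator standing in for
    clinical data, a small configurable encoder-decoder segmentation
    network with an atrous spatial pyramid, combined
    cross-entropy/Dice/distillation objectives, two-stage training with
    learning-rate decay and early stopping, IoU/PA/Dice evaluation, and a
    command-line interface for reproducible experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
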