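Package: colporeg
Title: Unsupervised Per-Channel Registration of Colposcopy Time Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised deformable registration of acetowhitening colposcopy
    time sequences. Each RGB channel is aligned by its own convolutional
    encoder-decoder that regresses a dense displacement field, applied through
    a differentiable bilinear spatial-transform layer and trained per sequence
    with a similarity loss plus a displacement-smoothness penalty; no
    registration ground truth is required. Includes a synthetic acetowhitening
    phantom generator with known rigid misalignments and masks, photometric
    data augmentation, Dice/IoU mask-overlap evaluation of registered versus
    unregistered sequences, and an end-to-end simulate-train-register-evaluate
    pipeline with a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
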