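Package: paleoseg
Title: Sparse-Annotation Deep Segmentation of Fossil Micro-CT Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments fossil material from the surrounding rock matrix in
    micro-CT slice stacks using a UNet trained on very sparse manual
    annotations (1-2% of slices). Implements the every-Nth-slice annotation
    protocol with midpoint refinement, positive-pixel-guaranteed crop
    sampling with a fixed negative-crop ratio, a compact convolutional
    encoder-decoder trained with AdamW under a warmup-plus-cosine-annealing
    schedule, Dice-monitored checkpointing, and full-slice inference with
    8-fold dihedral test-time augmentation. A seeded synthetic phantom
    generator produces fossil-in-matrix volumes with exact ground-truth
    masks so the complete workflow is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
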