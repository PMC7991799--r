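Package: woundkit
Title: Automated Segmentation and Closure Kinetics for Wound Scratch Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free quantification of wound (scratch) assay time-lapses.
    Enhances transmitted-light frames into a fluorescence-like image via a
    five-stage filter chain (intensity powering, difference-of-Gaussians flat
    field correction, local Shannon entropy, morphological top-hat, mean
    smoothing), segments the cell-free gap with a single tunable threshold
    coefficient applied to the histogram mean plus a central-cleft retry loop
    and biggest-central-blob selection, and turns per-frame gap areas into
    smoothed area-displacement series, per-edge velocities and linear-window
    regression fits with treatment-versus-control summaries. Includes a
    seeded synthetic time-lapse generator with per-frame ground truth so the
    whole pipeline is testable without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
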