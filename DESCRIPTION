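Package: lateralline
Title: Quantitative Analysis of Aminoglycoside-Induced Hair-Cell Death in the
    Zebrafish Lateral Line
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for distinguishing acute from delayed
    aminoglycoside-induced death of zebrafish lateral-line hair cells.
    Provides 3D segmentation of neuromasts, hair cells and endolysosomal
    vesicles from multichannel fluorescence stacks (multi-scale spot and
    filament detectors, Sauvola local thresholding, seeded watershed),
    vesicle-to-cytoplasm drug-accumulation ratios, GCaMP/RGECO calcium
    transient classification with a two-standard-deviation responder rule,
    Hill-curve HC50 dose-response estimation on per-fish hair-cell counts,
    and a synthetic-data generator producing image phantoms, calcium traces
    and overdispersed count tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    minpack.lm,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
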