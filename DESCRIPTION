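Package: annotqc
Title: Annotation Quality Assessment for Multi-Rater OCT Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the quality of multi-rater binary
    segmentation masks on optical coherence tomography (OCT) B-scans.
    Fuses rater annotations into a majority-vote consensus, computes
    pixel-level agreement metrics (IoU, Dice, sensitivity, specificity,
    precision, Cohen's kappa and two variants of Gwet's AC1), analyses
    annotation boundary intensities, estimates the Poisson speckle-noise
    shape parameter of each scan, and stratifies annotation quality by
    retinal zone and noise level. A synthetic-data module generates
    OCT-like phantoms with known fluid-region truth and simulated
    annotators with experience-dependent error, so the full pipeline can
    be exercised and validated without clinical images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
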