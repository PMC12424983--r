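Package: isletca
Title: Beta-Cell Cytosolic Calcium Imaging Analysis for Pancreatic Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cytosolic Ca2+ imaging of pancreatic islet
    beta cells in acute tissue slices: ROI segmentation of XYT fluorescence
    stacks from a statistical image, photobleaching correction (F/F0),
    multi-timescale oscillatory event detection with FWHM halfwidth and
    inter-event-interval kinetics, per-condition kernel-density summaries and
    two-sample tests, four-parameter logistic dose-response fitting
    (EC50/Hill), functional beta-cell network reconstruction from trace
    cross-correlations with graph metrics, and quantification of
    mitochondria-ER contact sites and ER surface-area-to-volume ratios from
    electron-microscopy segmentation masks. Includes ground-truthed synthetic
    data generators (coupled oscillatory trace populations, islet movies,
    dose-response tables, organelle mask layouts) so every stage is testable
    without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
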