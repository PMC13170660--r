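Package: iglonquant
Title: Quantification Pipeline for Autoantibody-Induced Neuronal
    Hyperactivity and Tau Missorting Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cell-level quantification stack for neuronal autoantibody
    assays: conversion of ROI fluorescence time series to dF/F0 with a
    percentile-window baseline, template-matching detection of calcium
    transients, control-referenced hyperactivity classification
    (mean + 2 SD of the control group), somatodendritic Tau-missorting
    mean-intensity statistics, surface-cluster density and size on
    dendrite masks, tangle-fraction counting, and one-site antibody
    binding (Kd) fits. Includes a synthetic-data generator with known
    ground truth (Poisson spike trains rendered through a GCaMP6f-like
    indicator kernel, multi-channel microscopy images, binding curves)
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
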