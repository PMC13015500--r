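Package: fixnov
Title: Fixation-Locked Encoding of Semantic Novelty in Neural Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the semantic novelty of successive
    foveal fixation patches modulates fixation-locked neural responses
    during free viewing. Provides saccade and fixation detection from raw
    gaze traces (velocity/acceleration thresholds and median-filter /
    2-SD detectors with morphological closing and percentile-based
    fixation onsets), extraction of 5-degree foveal fixation patches and
    a battery of low- and mid-level visual features (luminance and color
    statistics, contrast and spectral energy, amplitude-spectrum slope,
    texture and shape descriptors, center-surround saliency, optical
    flow), semantic novelty as the cosine distance between embeddings of
    consecutive patches, scalp and intracranial preprocessing including
    broadband high-frequency amplitude, banded ridge temporal response
    function (TRF) encoding models with B-spline nonlinearities and
    sequential per-band regularization search, and a statistical layer
    (hierarchical bootstrap, FDR, spatiotemporal cluster permutation,
    TRF peak characterization). A seeded synthetic-data generator with
    known ground truth supports end-to-end validation without any
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    splines,
    signal,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
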