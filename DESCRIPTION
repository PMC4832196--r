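Package: vsdi
Title: Voltage-Sensitive Dye Imaging Analysis of Mouse Barrel Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for trial-based widefield voltage-sensitive dye imaging
    (VSDI) of rodent barrel cortex: delta-F/F normalization, blank-trial
    artifact subtraction and blood-vessel masking; whisker-evoked response
    mapping (barrel ROI detection, amplitude and latency metrics,
    concentric-ring spatial-spread profiles); population synchrony via
    seed-pixel spatial correlation maps with sliding-window Pearson
    correlations and spatial-shuffle null distributions; and nonparametric
    group comparisons between animal cohorts. A synthetic VSDI movie
    generator with recorded ground truth emulates the statistical structure
    of such recordings so that every stage of the pipeline can be validated
    without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
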