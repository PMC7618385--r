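Package: cochleaCa
Title: Quantification of Spontaneous Calcium Activity in the Developing Cochlea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon time-lapse recordings of
    spontaneous calcium activity in the pre-hearing mouse cochlea. Provides
    frame-quality triage, 3-D Gaussian denoising, rigid drift correction,
    segmentation workflows for inner hair cells (IHCs), supporting-cell
    calcium waves and spiral ganglion neuron (SGN) terminals, dF/F0 trace
    extraction, prominence-based transient detection with amplitude and
    full-width-at-half-maximum criteria, grouping of peaks into single- and
    multi-cell events, calcium-wave morphometry (area, duration, expansion
    and contraction speed, longitudinal and radial extents), Fisher
    z-averaged correlation-versus-distance analysis, and a synthetic-movie
    forward model with per-event ground truth for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
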