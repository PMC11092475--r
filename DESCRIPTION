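Package: thalamoloc
Title: Sensory Thalamic Localizer fMRI Analysis with Resting-State Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives participant-specific medial and lateral geniculate
    nucleus (MGN/LGN) functional regions of interest from clustered-sparse
    thalamic localizer task BOLD fMRI, and validates them with resting-state
    functional connectivity. Includes sparse-acquisition design-matrix
    construction and OLS estimation, thalamic search-region construction
    from segmentation labels, partial-correlation coactivation mapping with
    adaptive thresholds, resting-state post-processing (mode-1000
    normalization, volume censoring, zero-phase band-pass filtering),
    ROI-pair and seed partial-correlation connectivity with selectivity
    tests, and a synthetic phantom generator with ground truth so the whole
    pipeline is testable without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
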