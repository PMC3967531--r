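Package: nativefc
Title: Native-Space Resting-State fMRI Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for hemisphere-resolved default-mode-network
    functional connectivity from resting-state BOLD fMRI analysed in each
    subject's native anatomical space. Provides motion quality control with
    framewise displacement and intensity-based RMSD, volume scrubbing by
    linear interpolation, zero-phase band-pass filtering, nuisance
    residualization, subject-specific regional signal extraction from label
    volumes, Fisher-Z pairwise connectivity with an interhemispheric
    averaging variant, group comparison with Bonferroni control, cognition
    regressions, and overlay-map quantification of cross-subject mask
    alignment. Ships a synthetic cohort generator that emulates a
    young/elder resting-state study design so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
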