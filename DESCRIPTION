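Package: strokecall
Title: Stroke Recognition in Medical Helpline Calls from Transcript Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end, fully synthetic re-implementation of a
    machine-learning pipeline for recognising stroke in medical helpline
    call transcripts. Provides a cohort generator emulating helpline and
    emergency-line call registries, registry linkage with onset time
    windows, bag-of-words word and character n-gram features, an ensemble
    of multi-layer perceptrons with fold-rotated early stopping,
    call-taker-matched threshold calibration with logit centring,
    permutation and bootstrap evaluation against simulated call-takers,
    and occlusion-based word attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
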