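Package: cogspeech
Title: Interpretable Detection of Cognitive Impairment Indicators from
    Spontaneous Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A modular three-stage pipeline for screening cognitive
    impairment from a speech sample. Stage 1 runs detectors for five
    clinically motivated indicators -- filler speech, repetitive speech,
    substitution errors, vague speech, and speech delays -- on a diarized
    CHAT-dialect transcript and the matching audio waveform. Stage 2
    aggregates detections into a small set of interpretable summary
    features (rates, inter-event distances, silence statistics). Stage 3
    predicts cognitive impairment with a cross-validated gradient-boosted
    stump classifier whose per-feature contributions yield an explainable
    diagnostic profile. Includes a CHAT parser, an amplitude-threshold
    silence detector, a masked-language-model scoring scheme with
    pluggable backends, and a synthetic-cohort generator so the whole
    pipeline is testable without access-restricted clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    xgboost,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
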