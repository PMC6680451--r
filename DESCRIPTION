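Package: phraseseg
Title: Acoustic Cue Models and Keypress Matching for Prosodic Phrase Segmentation
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing phrase-boundary segmentation of speech and
    speech-derived (delexicalized) pitch streams. Detects virtual segmentation
    points under seven rule-based acoustic cue models (pauses, pitch breaks,
    pitch rises and drops, and pause-plus-movement combinations), matches
    participant keypress segmentations against the models with the
    Russell-Rao binary similarity coefficient, computes segment-length
    statistics, and provides the mixed within/between ANOVA layer with
    partial eta squared. Includes a parametric generator of synthetic
    stimuli and simulated keypress responders so that the entire pipeline
    can be exercised and validated without access to audio recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
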