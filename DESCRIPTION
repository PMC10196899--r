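Package: moodwear
Title: Mood-Episode Classification from Wrist-Wearable Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fully automated pipeline for preprocessing raw multichannel
    physiology from Empatica-E4-style wrist wearables and classifying mood
    episode severity and polarity. Includes session archive input/output, a
    rules-based quality-control filter for invalid electrodermal activity,
    skin temperature and heart-rate readings, time alignment of channels to a
    one-second grid, fixed-length windowing with balanced train/validation/
    test/generalization partitions, a bidirectional long short-term memory
    classifier trained with Adam, per-channel permutation feature importance
    with Kendall W rank agreement, mutual-information association between
    channels and psychometric scale items, and a synthetic cohort generator
    with plantable signal artifacts for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
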