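Package: casync
Title: Network Synchrony in Developing Hippocampus and Seizure EEG Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies spontaneous network activity in calcium-imaging movies
    of the developing hippocampus and seizure metrics in adult EEG recordings.
    Provides PCA/ICA cell extraction from fluorescence movies, photobleaching
    correction by a cubic support line fitted beneath each trace (linear
    programming), SD-threshold calcium-event detection, PCA-based synchronous
    event (SE) and burst detection with a +/-984 ms participation window,
    per-movie activity summaries, FFT band power and cumulative power of
    epoched EEG with automated seizure-onset calls, ROUT outlier screening,
    and mixed-model group comparisons with Dunnett adjustment. A synthetic
    data generator with full ground truth supports validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    boot,
    lme4,
    lmerTest,
    emmeans,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
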