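Package: frsp
Title: Fixation-Related Spectral Perturbation Analysis of Sentence Reading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing oscillatory EEG dynamics during natural
    sentence reading with co-registered eye tracking. Implements word-level
    eye-movement reading measures (first-fixation duration, gaze duration,
    total viewing time) with standard exclusion rules, Hanning-tapered
    constant-cycle wavelet time-frequency decomposition, fixation- and
    sentence-locked spectral perturbation (dB log-ratio against a
    pre-event baseline), electrode-cluster/frequency-band/time-window
    aggregation with repeated-measures ANOVA, planned contrasts and
    per-subject linear-trend slope tests. Includes a calibrated synthetic
    generator for stimulus corpora, fixation scanpaths and 64-channel EEG
    with injected band-limited power modulations, so the whole pipeline is
    testable end to end without recorded data, plus readers and writers
    for BrainVision recordings and tab-separated fixation event tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
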