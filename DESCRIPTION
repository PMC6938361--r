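Package: debcr
Title: Trial-Level EMG Scoring and Simulation for Long-Delay Eyeblink Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores orbicularis oculi EMG recordings from long-delay eyeblink
    conditioning (dEBC) experiments at the single-trial level: full-wave
    rectification, leaky integration with a 1-ms time constant, per-trial
    baseline z-scoring, supra-threshold epoch detection with a minimum-duration
    gate, hyperactivity-trial exclusion, and classification of conditioned
    responses (CRs) into short-, middle- and late-latency windows. Aggregates
    trials into per-subject, per-session CR percentage, peak amplitude and
    latency summaries, and tests group-by-session effects with mixed and
    one-way repeated-measures ANOVA followed by LSD post hoc contrasts. A
    synthetic cohort generator produces band-limited EMG noise with injected
    CR, unconditioned-response and spontaneous-blink bursts under a logistic
    learning model, so the full pipeline runs and is testable without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rlang,
    tibble,
    dplyr,
    tidyr,
    signal,
    jsonlite,
    arrow
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
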