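Package: hypnoscore
Title: Rule-Based Sleep Staging, PIR Sleep Scoring and Circadian
    Summaries for Rodent Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing rodent sleep across the light/dark cycle:
    rule-based staging of EEG/EMG recordings into Wake/NREM/REM in 4-second
    epochs from band-dominance fractions and EMG amplitude; sleep scoring of
    passive-infrared (PIR) activity traces by the 40-second inactivity rule
    with sleep-bout analytics; hourly and 12-h light/dark summaries of
    hypnograms and sleep vectors; drinking-water dose arithmetic; and
    group-comparison statistics (pooled-variance t-tests, split-plot
    mixed-design ANOVA, and permutation alternatives). A synthetic-data
    generator produces hypnograms from phase-switching Markov chains,
    state-conditioned EEG/EMG signals, and PIR traces, so every stage of the
    pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
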