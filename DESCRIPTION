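Package: dtsleep
Title: Vigilance-State Scoring and Sleep Architecture Analysis for Mouse EEG/EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic vigilance-state scoring of two-channel mouse
    polysomnography (EEG + EMG) sampled at 128 Hz. Implements 4-second epoch
    spectral analysis (delta/theta/alpha/beta band powers, band fractions, EMG
    integral), a five-state epoch classifier covering wake, NREM sleep, REM
    sleep, cataplexy and DT sleep (a brief behavioral-arrest state with
    simultaneously elevated delta and theta power out of sustained
    wakefulness), sleep-architecture statistics (bouts, light/dark phase
    summaries, fold differences, hourly bins, NREM-to-REM transition windows),
    and a seeded semi-Markov synthetic recording generator with ground-truth
    hypnograms for validating every pipeline stage. Reads and writes EDF and a
    raw-binary fallback, plus TSV hypnograms and CSV summaries.
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
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
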