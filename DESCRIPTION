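Package: stressvep
Title: Frequency-Tagged EEG, ERP, and Autonomic Analysis of Acute Stress Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for acute-stress psychophysiology
    experiments that combine frequency-tagged steady-state visual evoked
    potentials (ssVEPs), event-related potentials (P1, N170, EPN, LPP),
    frontal alpha event-related desynchronization, skin conductance and
    heart-rate scoring, and salivary hormone summaries. Provides a
    synthetic-data generator with known ground truth for every measure, EEG
    preprocessing (zero-phase filtering, epoching, artifact rejection,
    average reference, channel interpolation), Morlet wavelet and FFT
    amplitude estimation, attentional bias scores for competing lateralized
    stimuli, trough-to-peak skin conductance scoring, area-under-the-curve
    hormone summaries, and a split-plot repeated-measures ANOVA layer with
    Greenhouse-Geisser correction, partial eta squared, and Bonferroni
    post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    pracma
Config/testthat/edition: 3
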