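Package: streamseg
Title: Simulation and Analysis of Temporal Fine Structure and Concurrent
    Vowel Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditory stream segregation experiments of the
    TFS1 family: synthesis of band-limited harmonic and frequency-shifted
    inharmonic complex tones with a pink-noise masker, a transformed
    up-down (2-down/1-up) two-interval forced-choice adaptive staircase
    with reversal-based threshold estimation and a constant-stimuli
    fallback, Klatt-style cascade formant synthesis of steady-state
    vowels and concurrent vowel pairs separated by semitone F0
    differences, single/double-correct scoring, simulated psychometric
    listener cohorts, and the matching statistical layer (Shapiro-Wilk
    normality checks, pooled independent t tests, mixed
    between-by-within repeated-measures ANOVA with Bonferroni-adjusted
    per-condition comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
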