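Package: taprate
Title: Respiratory Rate Estimation from Tap Intervals with Consistency-Based Quality Control
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates respiratory rate (breaths per minute) from the timestamps of
    screen taps made in time with a subject's breathing. The rate is 60 s divided by
    the median of a sliding set of z inter-tap intervals; a set is only reported when
    its consistency (maximum percentage deviation of any interval from the set median)
    falls at or below a threshold, which rejects aberrant taps on the fly. The package
    includes a seeded synthetic tap-stream simulator emulating observers tapping along
    with breathing subjects, accuracy (NRMSE) / efficiency / completion-rate evaluation
    with Bland-Altman agreement statistics, a (z, Th_C) sensitivity grid, and
    cost-function optimization of the accuracy-efficiency trade-off via k-fold
    cross-validation, plus CSV/JSON input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
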