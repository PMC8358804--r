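Package: efferentquant
Title: Quantitative Analysis of Cochlear Efferent Terminals and
    Noise-Induced Threshold Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for studying temporary noise-induced
    hearing loss and its modulation of the medial olivocochlear efferent
    system. Implements auditory brainstem response (ABR) threshold calling
    by a baseline mean +/- 2 SD criterion inside the 1.4-5 ms latency
    window, cochlear place-frequency mapping along a traced spiral-bundle
    polyline, density-threshold segmentation and morphometry of
    ChAT-immunoreactive terminal buttons, field-normalized optical
    densitometry with an 11-step gray-to-OD calibration, immune-cell
    counting, and the matching group-statistics battery (Friedman with
    Dunn-Bonferroni post hoc, Mann-Whitney, one- and two-way ANOVA with
    Bonferroni and Games-Howell post hocs, Pearson/Spearman correlation).
    A synthetic-data generator produces ABR waveform series and cochlear
    surface-preparation images with known ground truth, so the whole
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    png,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
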