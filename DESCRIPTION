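Package: sonifex
Title: Sonification of Gene Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transforms multi-sample log2 gene expression matrices into
    melodies: signal intensities are mapped to keys of a virtual
    equal-temperament keyboard (pitch), per-probe variance of the derived
    frequencies is quantized to classical metric note values (duration),
    and probe sets are ordered by the frequency of a median pseudo-sample
    so that sample-specific expression surfaces at the melody boundaries.
    Includes variance and group-specificity pre-filters, recalibration of
    melodies against well-known reference themes with per-sample frequency
    ratios preserved, 16-bit PCM WAV synthesis (mono and median-vs-sample
    stereo), LilyPond score export, frequency-course and divergence plots,
    a seeded synthetic-data generator with planted markers and an outlier
    sample, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
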