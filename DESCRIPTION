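Package: gaitsynergy
Title: Muscle Synergy Analysis of Walking EMG by Nonnegative Matrix
    Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts muscle synergies from multi-channel surface
    electromyography (EMG) recorded during walking. Implements the linear
    envelope preprocessing chain (band-pass filtering, full-wave
    rectification, low-pass smoothing, per-cycle submaximal normalization
    and time normalization to 101 points of the gait cycle), nonnegative
    matrix factorization by multiplicative updates with seeded restarts,
    variance-accounted-for (VAF) based selection of the number of
    synergies, and cross-group comparison of synergy activation
    coefficients and relative muscle weights (Pearson similarity bands,
    independent-samples t-tests, Shapiro-Wilk normality). Includes a
    synthetic EMG cohort generator with known ground-truth synergy
    structure so the whole pipeline is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
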