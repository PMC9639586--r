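Package: trillr
Title: Trill Performance Metrics and Sex Comparison of Birdsong
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement and inference chain for quantitative sex
    comparisons of songbird vocal performance, built around the blue tit
    (Cyanistes caeruleus) song phenotype: note-level spectral descriptors
    from mean power spectra, trill performance scores (trill rate, trill
    length, vocal consistency by spectrogram cross-correlation, and vocal
    deviation from an upper-bound rate-bandwidth regression), repertoire
    comparison with date-matched sample balancing, and a statistical stage
    with a log-link binomial GLM of singing context and Gaussian mixed
    models ranked by AICc with full-model averaging. A seeded synthetic
    song generator (waveforms, label tracks, and metadata tables) drives
    the whole pipeline so every stage is testable without field
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
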