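Package: ofrkit
Title: Dichoptic Ocular-Following Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for ocular-following responses (OFRs)
    recorded under dichoptic stimulation with binocularly correlated and
    anticorrelated random-line stimuli. Provides band-limited random-line
    stimulus generation with raised-cosine low-pass filtering and RMS
    contrast normalization; a synthetic session generator (trial-level
    displacement tables and rendered near-infrared camera-frame triplets
    with known ground truth); subpixel pupil and head-marker tracking;
    iterative robust (scaled-MAD) trial exclusion; and per-condition OFR
    summaries with direction tests and a four-cell bootstrap comparison of
    correlated versus anticorrelated responses used to flag interocular-
    correlation sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
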