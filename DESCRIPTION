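Package: orthopop
Title: Linear Population Decoding of Orthographic Stimuli from Visual Neural Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether a high-level visual neural population
    supports orthographic tasks via linear readout.  Provides orthographic
    stimulus construction (four-letter words, pseudowords and single letters
    rendered as binary glyph images with size, case and position variations),
    a synthetic neural-population generator with letter-by-position tuning,
    a cross-validated linear decoding battery (word classification, invariant
    letter and bigram identification), signal-detection behavioral metrics
    with noise-adjusted consistency, single-site selectivity, sparsity and
    topography statistics, letter-to-string encoding reconstruction models,
    and a mirror-symmetry reflectivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
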