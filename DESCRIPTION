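Package: spectrodict
Title: Unsupervised Spectro-Temporal Feature Learning for Bird Sound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A classification workflow for bird sound recordings built around
    unsupervised dictionary learning on Mel spectrograms. Audio is converted to
    non-overlapping Hamming-windowed Mel spectral frames (40 bands above 500 Hz,
    RMS-normalised), optionally denoised by median spectral subtraction, and
    projected onto an overcomplete basis learned by online streaming spherical
    k-means over stacked spectro-temporal patches (single- or two-layer with
    temporal max-pooling). Variable-length feature sequences are summarised by
    mean and standard deviation, maximum, or modulation coefficients, and
    classified by a 200-tree random forest in single-label, binary-relevance or
    multilabel mode, with optional decision-window pooling. Includes crossvalidated
    AUC and mean-average-precision evaluation, a seeded synthetic soundscape
    generator for end-to-end testing, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
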