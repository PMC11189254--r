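Package: hipposeq
Title: Online One-Shot Storage and Cued Retrieval of Pattern Sequences in
    a Hippocampal Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rate-based model of the hippocampal circuit (EC, DG, CA3) that
    stores sequences of binary patterns online and in one shot by
    hetero-associating them with a pre-trained intrinsic sequence in CA3,
    using the Hebbian descent learning rule on centered neurons. Provides
    synthetic pattern-sequence generators (uncorrelated and temporally
    correlated), a generic dentate-gyrus pattern separator, a sensory
    binarizing codec, cued retrieval with sequence relaxation, offline
    replay, capacity estimation, and a recurrent-plasticity baseline for
    comparison.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
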