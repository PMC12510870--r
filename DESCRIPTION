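Package: cryoconsensus
Title: Consensus Latent Spaces for Cryo-EM Conformational Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges two or more independently estimated per-particle cryo-EM
    conformational landscapes (latent coordinate matrices from heterogeneity
    analysis methods) into a single consensus latent space using a
    multi-encoder/multi-decoder neural network trained with a four-term loss:
    cross-space reconstruction error, pairwise latent agreement, a
    Sammon/Shannon-style distance-preservation stress, and a Wasserstein
    penalty on pairwise-distance distributions. Provides per-particle
    consensus and representation error metrics, conversion between landscape
    representations, a sliced-Wasserstein permutation test for selecting a
    statistically validated consensus particle set, and a synthetic landscape
    generator with planted ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
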