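Package: dpcnet
Title: Dynamic Predictive Coding Networks for Hierarchical Sequence Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements dynamic predictive coding, a hierarchical
    spatiotemporal generative model of visual sequences in which a
    higher-level latent state modulates the transition dynamics of a
    lower-level sparse code through a hypernetwork. Provides MAP inference
    by per-step gradient-based prediction-error minimization, parameter
    learning on image-sequence corpora, synthetic stimulus generators
    (moving sprites, bouncing dynamics, white noise, drifting whitened
    textures), response analyses (reverse-correlation space-time receptive
    fields, autocorrelation timescales, decoding), a flash-lag /
    postdiction simulation, a Hebbian associative memory for cue-triggered
    sequence recall, and a three-level extension with threshold-gated
    second-level transitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
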