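Package: genmem
Title: Generative Models of Memory Construction and Consolidation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates systems consolidation as teacher-student transfer from a
    hippocampal autoassociative store to a neocortical generative network.
    One-shot episodic encoding is modelled with a continuous modern Hopfield
    network; replay from random-noise queries trains a variational autoencoder
    whose latent variables support semantic readout, imagination (interpolation,
    vector arithmetic, category sampling) and schema-based recall. An extended
    model splits each event into conceptual latents plus unpredicted sensory
    detail gated by per-pixel reconstruction error, reproducing memory
    distortions: prototypicality effects, boundary extension and contraction,
    context-driven distortion of ambiguous stimuli, and DRM false memory.
    Includes generators for factorized synthetic scenes, digit-like glyphs and
    topic-structured word corpora, plus lesion toggles for simulating amnesia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    e1071,
    EBImage,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
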