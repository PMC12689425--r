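Package: sparsecone
Title: Simulation, Sparse-Sampling Restoration and Quantification of Cone
    Photoreceptor Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying AI-assisted sparse-sampling strategies in
    adaptive optics optical coherence tomography (AOOCT) imaging of the cone
    photoreceptor mosaic. Simulates en-face cone mosaics and layered
    outer-retina volumes with known ground-truth spacing, degrades them by
    lateral sparse sampling, restores them with a residual-in-residual
    windowed-attention transformer GAN (implemented natively, trainable at toy
    scale on one CPU) or interpolation baselines, and quantifies restoration
    fidelity with circumferentially averaged power-spectral-density cone
    spacing and contrast, edge-directionality pixelation scores, PSNR, paired
    one-tailed t-tests, and paraxial model-eye pixel-to-micrometre scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
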