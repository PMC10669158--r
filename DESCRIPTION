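Package: leafdiffuse
Title: Mask-Guided Generative Augmentation for Plant-Disease Leaf Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for synthesising plant-disease leaf images with
    mask-guided generative models. Implements the denoising diffusion
    probabilistic model (DDPM) forward and reverse processes with a
    RePaint-style mask-conditioned inpainting sampler, the InstaGAN
    instance-aware translation loss family, mask preparation utilities
    (Otsu leaf segmentation, morphological dilation, split-mask
    catalogues, convention-safe inversion, mean IoU scoring), the
    standard generative evaluation metrics (PSNR, SSIM, Inception
    Score, FID, KID) over pluggable feature extractors, a procedural
    synthetic-leaf dataset generator with ground-truth masks, and an
    end-to-end pipeline with a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
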