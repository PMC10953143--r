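Package: decontrast
Title: Contrast-Removal Translation of 3D T1-Weighted Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to synthesize non-contrast-enhanced (T1nce) from
    contrast-enhanced (T1ce) T1-weighted 3D brain MRI at desk scale.
    Provides a seeded paired brain-phantom generator with ground-truth
    tissue maps and graded quality degradation, standard preprocessing
    (min-max rescaling, centred cropping, trilinear resampling, quality
    labelling, train/test splitting), three 3D U-Net generator variants
    (residual, attention-gated, transformer-bottleneck) trained with an
    L1 objective or as a patch-based conditional GAN with soft labels,
    and a two-tier validation suite: brain-masked image similarity
    (MAE, PSNR, SSIM with paired t-tests and Bonferroni correction) and
    tissue-volume fidelity (GM/WM/CSF volumes, absolute and signed
    volume differences normalized by total intracranial volume, Dice
    overlap) using a simple intensity-based tissue segmenter. Networks
    are implemented with a compact reverse-mode automatic
    differentiation tape and compiled 3D convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
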