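Package: MetaboSR
Title: Super-Resolution Reconstruction of MRSI Metabolite Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to upsample low-resolution magnetic resonance
    spectroscopic imaging (MRSI) metabolite maps by a factor of four.
    Includes a synthetic brain-phantom simulator that composes gray
    matter, white matter, CSF and tumor tissue fractions into metabolic
    maps, a k-space (Fourier) truncation degradation model, a measured
    data conditioning chain (spectral-quality filtering, harmonic
    inpainting, nonlocal-means denoising, metabolite ratio maps),
    classical upsamplers (bicubic, weighted total variation, feature
    nonlocal means with anatomical priors), a compact CPU
    implementation of a Unet generator and GAN discriminator with
    Adam training, and full-reference image quality metrics (PSNR,
    SSIM, FSIM) with Mann-Whitney U group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'fourier.R'
    'phantom.R'
    'preprocess.R'
    'classical.R'
    'network.R'
    'deep.R'
    'metrics.R'
    'io.R'
    'pipeline.R'
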