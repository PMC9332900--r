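# MetaboSR

Super-resolution reconstruction of MRSI metabolite maps.

Magnetic resonance spectroscopic imaging (MRSI) maps brain metabolites —
including tumor markers such as d-2-hydroxyglutarate (2HG) in
IDH-mutant glioma — but must be acquired at coarse resolution (~5 mm
voxels) because metabolite signals are weak. MetaboSR upsamples
metabolite maps by a factor of 4 per in-plane axis, for researchers who
want sharper metabolic images without longer scans.

The acquisition is modeled as spectral truncation plus noise,

&nbsp;&nbsp;&nbsp;&nbsp;*I*<sup>LR</sup> = *A* *I*<sup>HR</sup> + *n*,

where *A* keeps the central block of the discrete Fourier spectrum
(k-space). The package provides:

* a **synthetic phantom simulator** — brain-like GM/WM/CSF/tumor
  segmentations composed into metabolic maps
  (0.1·GM + 0.12·WM + 0·CSF + τ·TM, τ ∈ {0.2, …, 0.8}, normalized to 1)
  and degraded through *A* into LR/HR training pairs;
* a **conditioning chain** for measured maps — spectral-quality
  filtering, harmonic inpainting, nonlocal-means denoising, and the
  HGG = (2HG+Gln)/Glu and TCN = tCho/tNAA ratio maps;
* **classical upsamplers** — bicubic initialization, (weighted) total
  variation against the exact degradation operator, and feature
  nonlocal means (FNLM) guided by co-registered anatomical MRI;
* a compact CPU **Unet generator / GAN discriminator** with
  backpropagation and Adam written over Rcpp kernels, training loops for
  pure-MSE (λ = 0) and adversarial (λ > 0) objectives, and the three
  prediction variants (deep learning alone, + FNLM, or with priors as a
  second input channel);
* **quality metrics** — PSNR, SSIM, FSIM — and Mann–Whitney U group
  comparisons with percent-improvement tables.

## Worked example

A miniature end-to-end run — simulate phantoms, train a small Unet,
compare it with bicubic and weighted TV on held-out slices:

```r
library(MetaboSR)

cfg <- runConfig(seed = 7, outputDir = tempfile("demo"),
                 nTrain = 24, nTest = 4, gridDim = c(64, 64),
                 methods = c("bicubic", "wtv", "unet"),
                 train = list(iterations = 300, batchSize = 8,
                              learningRate = 1e-3, depth = 2,
                              baseChannels = 8, cropSize = NULL))
report <- runPipeline(cfg)
report
```

```
MetricReport (baseline: bicubic )

  method metric    mean
 bicubic   FSIM  0.8064
    unet   FSIM  0.9468
     wtv   FSIM  0.9623
 bicubic   PSNR 20.0077
    unet   PSNR 32.8930
     wtv   PSNR 34.7687
 bicubic   SSIM  0.6857
    unet   SSIM  0.9351
     wtv   SSIM  0.9730

Improvement over baseline (% of group mean):
 metric method baselineMean    mean improvementPct pairedImprovementPct
   PSNR    wtv      20.0077 34.7687          73.78                75.13
   PSNR   unet      20.0077 32.8930          64.40                65.75
   SSIM    wtv       0.6857  0.9730          41.89                42.63
   SSIM   unet       0.6857  0.9351          36.36                37.11
   FSIM    wtv       0.8064  0.9623          19.33                19.39
   FSIM   unet       0.8064  0.9468          17.41                17.49

Mann-Whitney U vs baseline (* p < 0.05):
 metric method  U       p significant              test
   PSNR    wtv 16 0.02857        TRUE exact enumeration
   PSNR   unet 16 0.02857        TRUE exact enumeration
   SSIM    wtv 16 0.02857        TRUE exact enumeration
   SSIM   unet 16 0.02857        TRUE exact enumeration
   FSIM    wtv 16 0.02857        TRUE exact enumeration
   FSIM   unet 16 0.02857        TRUE exact enumeration
```

Read: at this miniature 64×64 scale the ×4 degradation is harsh —
bicubic manages 20 dB while both reconstruction methods recover over
12 dB more. Weighted TV slightly outruns the 300-iteration Unet here
because piecewise-constant phantoms are TV's ideal case; at the full
benchmark scale (128×128, 1500 iterations — see below) the Unet leads.
Per-image values, the summary and the improvement table are also written
as TSV files into the output directory alongside the exact configuration
and a stage log.

Single maps upsample directly:

```r
sr <- predictSR(trainedModel, lrMap, method = "dl1")     # Unet alone
sr <- predictSR(trainedModel, lrMap, prior = priors,     # Unet + FNLM
                method = "dl2")
```

A thin command-line front end with verbs `simulate`, `preprocess`,
`train`, `upsample`, `evaluate`, `all` ships in `inst/cli/metabosr`.

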