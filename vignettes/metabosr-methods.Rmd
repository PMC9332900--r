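---
title: "MetaboSR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MetaboSR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(MetaboSR)
```

## The problem

Magnetic resonance spectroscopic imaging (MRSI) maps metabolite
concentrations across the brain, but low metabolite signal forces
acquisition at coarse resolution (voxels around 5 mm in plane), blurring
lesion boundaries and hiding small structures. MetaboSR implements a
super-resolution pipeline that upsamples metabolite maps by a factor of 4
per in-plane axis: simulated training data from tissue segmentations,
classical upsamplers (bicubic, weighted total variation, feature nonlocal
means with anatomical priors), a Unet generator optionally fine-tuned
adversarially, and full-reference quality metrics with nonparametric group
statistics.

Three deep-learning variants are exposed by `predictSR()`:

* **dl1** — the generator applied to the bicubic-initialized map alone;
* **dl2** — dl1 followed by FNLM reinterpolation guided by prior MRI;
* **dl3** — the generator applied to the channel-stacked map and priors.

## The acquisition (degradation) model

The forward model treats a low-resolution acquisition as spectral
truncation of the underlying high-resolution image plus noise:
\[
I^{LR} = A\,I^{HR} + n,
\]
where \(A\) retains the central block of the discrete Fourier spectrum
(`fftDownsample()`), and \(n\) is i.i.d. Gaussian (`addNoise()`). Per axis
with output length \(m\), the retained band is the negative-inclusive set
\(-m/2,\dots,m/2-1\). At the band edge we use a Hermitian-consistent
convention: truncation folds the \(+m/2\) source coefficient into its
alias \(-m/2\); zero-filled upsampling splits the \(-m/2\) coefficient
half onto \(\pm m/2\). Consequences, both exact to rounding: real images
stay real, and `fftDownsample(fftUpsample(x, f), f) == x`. Scaling is
DC-preserving (a constant maps to the same constant). Arbitrary target
grids are supported by `fftResample()` (e.g. 256×256 → 184×184), with
integer-factor wrappers enforcing divisibility.

A property worth knowing: \(A\) is **not equivariant under array
mirroring** on even grids. Reversing index order on the high-resolution
grid and on the low-resolution grid reflects about continuous centers
that differ by half an LR voxel minus half an HR voxel, so
\(A(\mathrm{flip}\,x) \ne \mathrm{flip}(A\,x)\) — the discrepancy on
sharp-edged images is large (order 1 on unit-range phantoms). This is why
mirror augmentation is off by default in training (below).

## Synthetic phantoms

`makeSegmentation()` draws a brain-like 2D slice: a deformed-ellipse head
outline (low-order random angular perturbation), a thin outer CSF rim, a
cortical gray-matter ribbon whose inner boundary is folded by
higher-frequency angular terms (sulcus-like), a white-matter core, two
ventricular CSF blobs, and 0–N tumor blobs placed in deep white matter.
Hard labels receive a Gaussian partial-volume blur (σ = 1 voxel, kernel
normalized to unit sum under zero extension), so fractions stay in [0, 1]
and sum to at most 1 per voxel by construction.

`composeVHR()` turns fractions into a metabolic map with fixed tissue
weights

\[
\mathrm{map} = 0.1\,\mathrm{GM} + 0.12\,\mathrm{WM} + 0\,\mathrm{CSF}
             + \tau\,\mathrm{TM},
\]

with the tumor weight τ drawn from the discrete grid 0.2–0.8 (step 0.1)
and the result normalized to a maximum of 1. One τ applies per phantom.
Two high-resolution ground-truth modes exist (`makeHRTruth()`): k-space
truncation of the source map (sharp, mild Gibbs ringing) and FNLM
upsampling of the LR map with synthetic anatomical priors (smoother
edges). `generateDataset()` cycles τ round-robin, derives per-phantom
seeds from one master seed, and is a pure function of (config, seed). The
default grids are desk-scale: 128×128 HR slices with 32×32 LR inputs
(factor 4); full-scale 3D grids are reachable through the configuration
but not exercised by the test suite.

What the phantoms emulate: piecewise-near-constant tissue compartments
with fixed per-tissue intensities, partial-volume boundaries, a tumor
compartment of variable intensity, and truncation blurring/ringing. What
they do not emulate: real anatomical geometry and its population
variability, pathology texture beyond an intensity compartment, spectral
fitting artifacts, B0/B1 inhomogeneity, and motion. Passing the package's
benchmarks therefore demonstrates that the pipeline inverts its own
degradation model on this compartment family — not clinical performance
on measured data.

Simulated LR maps add no noise by default (the composition recipe is
deterministic; the degradation-model noise term is available via
`noiseStd`).

## Measured-data conditioning

`preprocessLR()` chains the three conditioning steps used before any
upsampling: spectral-quality filtering (voxels with scores at or beyond a
threshold are marked missing — ties at the threshold always fail, making
the rule deterministic), harmonic inpainting (Jacobi iterations of
neighborhood means until the maximum update is below 1e-6; valid voxels
untouched), and nonlocal-means denoising (patch radius 1, search radius
5, bandwidth `h` on the intensity scale, weights
\(\exp(-\|p_i-p_j\|^2/h^2)\) with mean-squared patch distances).
`computeRatioMaps()` forms the tumor-contrast ratios
HGG = (2HG + Gln)/Glu and TCN = tCho/tNAA, flagging voxels whose
denominator falls below 1e-6 of the denominator maximum as invalid (NA)
rather than assigning an arbitrary value.

## Classical upsamplers

**Bicubic** (`bicubicUpsample()`): separable Keys cubic convolution
(a = −0.5), cell-centered alignment (HR center \(i\) at LR coordinate
\((i+0.5)/f-0.5\), 0-based), replicated edges, output clipped to
\([0, 1.05\max(\mathrm{lr})]\). Rows of the interpolation matrix sum to
1, so constants are exact.

**Weighted total variation** (`wtvUpsample()`): minimizes
\(\tfrac12\|Ax-y\|^2+\lambda\sum_i w_i\,\varphi_\varepsilon(\nabla x)_i\)
with \(A\) the truncation operator, forward-difference gradients,
\(\varphi_\varepsilon(g)=\sqrt{|g|^2+\varepsilon^2}\)
(ε = 1e-3), and weights \(w\equiv 1\) (plain TV) or
\(w=\exp(-|\nabla \mathrm{prior}|/\sigma_w)\) with
\(\sigma_w = \mathrm{median}(|\nabla \mathrm{prior}|)\) over nonzero
entries (wTV; several priors combine by the elementwise maximum gradient).
The solver is monotone accelerated gradient descent: Nesterov momentum,
backtracking line search on an Armijo condition, momentum restart
whenever a step fails to descend; the returned objective trace is
non-increasing by construction, ten consecutive non-descending proposals
raise a warning. Initialization is the bicubic map; λ = 0 yields the
least-squares data fit. The exact adjoint \(A^\top\) (transposed spectral
transfer matrices) is used in the gradient.

**Feature nonlocal means** (`fnlmReinterpolate()`): each HR voxel becomes
a convex combination of the initialized SR map over a search window, with
weights computed from patches of per-image z-scored anatomical priors —
similarity lives in the prior feature space, values come from the
metabolic map. The optional `lrConsistency` step adds
\(U(y - A\hat x)\), \(U\) being the zero-fill right inverse of \(A\), so
the output degrades exactly to the LR input. As \(h \to 0^+\) the filter
approaches the identity wherever prior features are distinct; exactly
tied patches (e.g. inside flat prior regions) keep weight 1 at any
bandwidth and legitimately average.

## The networks

The generator (`buildGenerator()`) is a fully convolutional Unet acting on
the bicubic-initialized HR grid: paired 3×3 convolutions per contraction
level, downsampling, a bottleneck, then 2×2 transposed convolutions with
skip concatenation, closed by a linear 1×1 convolution. Two variants
honor the two architecture descriptions: ReLU with max-pooling (the
Unet-only model) and parametric ReLU with strided convolutions (the GAN
generator). The input has 1 channel (the metabolic map) or 1+P channels
(map plus P priors, the dl3 two-input model). Desk-scale defaults are
depth 3, base 8 channels.

**Initialization.** Weights are He-initialized; by default a delta-kernel
path for input channel 1 is threaded through the level-1 encoder/decoder
and the final convolution, making the fresh network the exact identity on
non-negative inputs. Training then starts at the bicubic baseline and
learns corrections, which converges much faster inside short iteration
budgets. A zero final layer still yields a zero output (the final
convolution is the only path to the output).

The discriminator (`buildDiscriminator()`) follows the standard adversarial-SR
topology: eight 3×3 convolutional layers with kernel counts rising 64 to
512, stride-2 reductions exactly where channel counts double, two dense
layers and a sigmoid head; leaky-ReLU (slope 0.2) activations. Desk-scale
tests shrink the channel progression, not the topology.

**Loss** (`perceptualLoss()`): mean over the batch of the per-sample sum
of squared differences plus \(\lambda\,(-\log D(G(\cdot)))\). λ = 0 is
pure-MSE Unet training. The non-saturating generator form \(-\log D\) is
used for the adversarial term; the discriminator maximizes
\(\log D(\mathrm{real}) + \log(1 - D(\mathrm{fake}))\). λ defaults to
1e-3 for GAN fine-tuning (configurable; the adversarial weight is
otherwise unspecified).

**Training** (`trainUnet()`, `trainGAN()`): Adam. The full-scale recipe
recorded in the defaults is batch 16, learning rate 1e-4 for 20k
iterations (Unet), then GAN fine-tuning from the pretrained Unet at 1e-5
for the first half and 1e-6 for the second, momenta (0.9, 0.999).
"Until convergence" is replaced by an explicit iteration budget plus
optional early stopping on a validation-MSE plateau. Desk-scale
benchmarks shrink the budget to 1500 iterations and train on 64×64 HR
crops whose origins are drawn on the LR lattice (HR origin = 4 × LR
origin), keeping LR/HR alignment exact. Mirror augmentation is available
(`augmentPair()`, `flip = TRUE`) but off by default: because the
degradation is not mirror-equivariant (see above), flipped pairs pose a
slightly shifted inverse problem, and enabling flips measurably stalls
convergence within short budgets. GAN training with λ = 0 and a frozen
discriminator reproduces Unet training bit-for-bit on the same seed —
both paths share one minibatch loop and RNG stream. Discriminator score
saturation (all fake scores within 1e-3 of 0 or 1 over a 50-iteration
window) raises a collapse warning; training continues.

Runs are seed-deterministic on a fixed BLAS/thread configuration
(single-threaded linear algebra gives bit reproducibility). Checkpoints
are self-describing (format tag, version, architecture spec) and restore
predictions bit-exactly.

## Quality metrics and statistics

`psnr()` is \(10\log_{10}(R^2/\mathrm{MSE})\) with data range R = 1 on
normalized maps (identical images report `Inf`). `ssim()` uses the
standard Gaussian window (11×11, σ = 1.5) with stabilizers K = (0.01,
0.03), computed over fully interior windows. `fsim()` follows the
standard feature-similarity definition: Kovesi phase congruency (4
log-Gabor scales, minimum wavelength 6, multiplier 2, σ_onf 0.55; 4
orientations; noise compensation with k = 2) combined with Scharr
gradient-magnitude similarity, pooled by maximum phase congruency, with
T1 = 0.85 and T2 = 160 on a 0–255 scale. Inputs are rescaled by their
joint range, which makes the score invariant to a common global intensity
scaling; constant image pairs are degenerate and return 1 with a warning.
3D inputs are scored slice-wise and averaged.

`mannWhitneyU()` computes the exact two-sided p by enumerating all group
assignments when \(n_a+n_b\le 12\), otherwise a normal approximation with
tie and continuity corrections; an all-tied pooled sample yields p = 1.
`compareMethods()` aggregates per-image metrics into group means, percent
improvements over a designated baseline computed on group means (the
per-image paired mean is also reported), and U-tests per metric with
stars at p < 0.05.

## Benchmark configuration and problem sizes

The package's headline benchmark (`scripts/acceptance.R`, mirrored in the
test suite) generates 256 training and 32 held-out test slices at 128×128
(×4 factor), trains the depth-3, base-8 MSE Unet for 1500 iterations
(batch 16, Adam 1e-4, 64×64 crops, no flips, identity initialization) and
reports the relative improvement of mean PSNR/SSIM/FSIM over bicubic
interpolation on the test slices. Unit tests use 32×32 phantoms with
8×8 LR inputs and depth-2, base-4 networks. These sizes are the package's
chosen desk-scale study conditions; the full-scale schedule remains in
the configuration defaults.

## Known limitations

* Phantoms are 2D slices; 3D training is out of scope (k-space resampling
  and I/O handle 3D volumes).
* The FNLM here is a standard feature-NLM; the exact multi-scale weight
  scheme of dedicated FNLM implementations is not reproduced.
* Quality filtering accepts a generic per-voxel score; specific spectral
  quality criteria (CRLB, linewidth) are the caller's responsibility.
* Priors are assumed co-registered to the SR grid; no registration is
  performed, and misalignment (e.g. inter-scan motion) propagates into
  prior-guided methods.
* Metrics are computed over the full field of view by default; a brain
  mask can be supplied for PSNR.
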