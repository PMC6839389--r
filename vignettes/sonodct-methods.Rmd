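---
title: "Frequency-domain analysis of skin sonograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain analysis of skin sonograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonodct)
```

## The model

`sonodct` analyzes high-frequency (50 MHz) skin sonograms in the spatial
frequency domain. The physical premise is a statistical one: healthy skin
under coherent ultrasound shows *fully developed speckle* — granular
multiplicative interference whose spectrum is broadband — while hypoechoic
lesions are dark and spatially smooth, so their energy concentrates in the
low-frequency corner of the spectrum. Everything in the package is a
consequence of that contrast.

### From RF to B-mode

Raw radio-frequency samples are signed echo amplitudes. B-mode conversion is
the algebraic rectification

$$\mathrm{imgB} = 2\,|\mathrm{imgRF}| - \mathrm{offset},$$

with `offset` a device constant. No envelope detection, log compression or
gain compensation is applied — downstream spectral analysis assumes exactly
this rule, and `rf_to_bmode()` implements exactly it. Negative output pixels
(possible when `offset > 0`) are preserved; clipping happens only when an
image is rendered or written to a raster file.

### The orthonormal 2-D DCT

For an $M \times N$ image $A$, the type-II DCT with orthonormal scaling is

$$B_{pq} = a_p a_q \sum_{m=0}^{M-1}\sum_{n=0}^{N-1} A_{mn}
  \cos\frac{\pi (2m+1) p}{2M}\,\cos\frac{\pi (2n+1) q}{2N},
  \qquad a_0 = \sqrt{1/M},\; a_p = \sqrt{2/M}\ (p>0),$$

computed as $B = C_M A C_N^\top$ with cached orthogonal basis matrices, so a
transform costs two dense matrix products. Orthonormality gives two
properties the tests rely on: Parseval's identity
($\lVert B\rVert_F = \lVert A\rVert_F$) and exact invertibility
($A = C_M^\top B C_N$). $B_{00}$ is the DC term, $\sqrt{MN}$ times the image
mean; `remove_dc()` zeroes it when only alternating content should count.

### Classification features

A whole sonogram is reduced to the singular values of its log-absolute
spectrum:

$$ S = \operatorname{svd}\bigl(\log \max(|B|, \varepsilon)\bigr), $$

the economy-size SVD keeping $\min(M, N)$ values in descending order — 384
for the standard $1024 \times 384$ scan. The log makes the heavy-tailed
coefficient distribution tractable; the floor $\varepsilon = 10^{-12}$
(tunable in `extract_features()`) bounds the logarithm on exact-zero
coefficients, which flat image regions produce, contributing about $-27.6$
without distorting informative coefficients. Singular values are invariant
to transposition and capture the spectrum's energy layout rather than its
exact pattern.

**Normalization.** Features are normalized per index as
$(s_i - \mu_i)/\sigma_i$ with statistics from the training set only
(`feature_stats()`), persisted inside the trained model. One design choice
matters here: each $\sigma_i$ is floored at `scale_floor` (default 0.05)
times the largest per-index standard deviation. The trailing singular values
of sonogram log-spectra are nearly constant across images; plain z-scoring
divides their tiny, noise-dominated spread out and amplifies pure noise to
the same unit variance as the informative leading features. With hundreds of
such inputs feeding a small network, that amplified noise destabilizes
training. The relative floor keeps near-constant indices numerically small
while leaving well-spread indices ordinarily z-scored; `scale_floor = 0`
recovers plain z-scoring.

### The classifier

A feed-forward pattern-recognition network: input layer of feature length,
two hidden layers of 10 tanh units (`hidden = c(10, 10)`), softmax output,
trained on the cross-entropy loss by **scaled conjugate gradient** (SCG)
backpropagation. SCG is a batch method that sizes each conjugate-gradient
step from a one-dimensional quadratic model whose curvature is estimated by
a finite-difference Hessian–vector product, regularized Levenberg–Marquardt
style; it has no user learning rate, and accepted steps never increase the
loss. Weights initialize uniformly on $\pm 1/\sqrt{\text{fan-in}}$ from the
training seed; biases start at zero; training is fully deterministic given
the seed.

Two standard guards are configurable in `train()`:

* **Weight decay** (`regularization`, default 0.1): the performance function
  is $(1-r)\,\mathrm{CE} + \tfrac{r}{2}\sum w^2$ (biases unpenalized).
  Feature vectors are wide (hundreds of inputs) and labeled sonograms few,
  so shrinkage is the default; reported and validation losses are always the
  plain cross-entropy.
* **Early stopping**: a stratified validation split (`val_fraction`, default
  0.15) is monitored, training stops after `patience` (30) accepted steps
  without improvement, and the best-validation weights are kept. A
  stratified `test_fraction` (0.15) is reserved and untouched; its indices
  are stored in `training_meta$split` for honest held-out evaluation.

`evaluate()` reports the confusion matrix, per-class TP/FP/TN/FN counts and
percentages, accuracy, one-vs-rest ROC curves from an explicit threshold
sweep, and the trapezoidal AUC (equal to the normalized Mann–Whitney
statistic; the binary-problem AUC is the positive-class curve's).

### Segmentation

The image is tiled into `block_size` × `block_size` squares (default 32,
minimum 4; trailing partial blocks are cropped, never padded — padding would
inject artificial spectral content). Each block's **mean frequency** is the
mean absolute DCT coefficient with the DC term excluded, so the statistic is
invariant to adding a constant to the block. Healthy speckle is broadband
and scores high; smooth hypoechoic tissue scores low. One threshold per
image comes from Otsu's method on the 8-bit-style equal-width histogram
(256 bins) of the block statistics; blocks strictly above the threshold are
healthy.

**The contrast gate.** Otsu's criterion always produces a split, even when
the statistics are unimodal — an image with no lesion would still have
roughly half its blocks labeled suspicious. `segment()` therefore accepts
the split only if the candidate suspicious class is markedly darker in the
frequency domain:

$$\frac{\bar{s}_\text{healthy} - \bar{s}_\text{suspicious}}
       {\bar{s}_\text{healthy}} \ge \texttt{min\_contrast},$$

default 0.5. The default was set from the construction of the problem, not
fitted: lesion blocks score below a tenth of healthy blocks (contrast
> 0.9), while the layer-to-layer variation of healthy tissue stays under
about 0.3. The gate is scale-invariant, so segmentation commutes with
rescaling the image. A gated (or exactly constant, hence degenerate) image
yields an all-healthy map with a warning and a machine-readable
`no_lesion_reason`.

## Numerical choices

* Otsu candidates are the 255 interior bin edges; between-class variance is
  maximized in the algebraically simplified form
  $(\mu_T \omega_0 - m_0)^2 / (\omega_0 \omega_1)$ with cumulative sums;
  ties break toward the lowest threshold (`which.max`). The returned value
  carries the maximized variance and the effectiveness ratio (between / total
  variance) as attributes.
* Softmax is computed with log-sum-exp stabilization, and cross-entropy
  floors posteriors at `1e-300`; SCG aborts with a divergence error if the
  loss becomes non-finite, and restarts in the steepest-descent direction
  every `n_parameters` accepted steps.
* Block ground truth from a pixel mask uses a majority rule: a block is a
  lesion block when at least half its pixels are lesion (`block_mask()`).
* All seeded routines (`with_seed` internally) restore the caller's RNG
  state, so library calls never perturb user randomness, and every seeded
  pipeline rerun is bit-identical.
* Degenerate and invalid inputs raise classed conditions
  (`sonodct_*_error`), so callers can distinguish configuration, format,
  numeric, and degeneracy failures programmatically.

## The phantom generator

`generate_phantom()` emulates the *echo statistics the method exploits*, not
acoustic physics:

* three tissue layers (boundaries at depth fractions 0.10 / 0.45 by default)
  with decreasing echogenicity 190 / 165 / 140, multiplied by unit-mean
  gamma speckle (shape 6, coefficient of variation ≈ 0.41) — bright,
  broadband, spatially uncorrelated;
* lesions (`lesion_spec()`: rectangle or ellipse) that replace tissue with
  `drop` times the layer intensity, modulated by a Gaussian-smoothed
  heterogeneity field (`smooth_sigma` default 16 px, at or above half the
  analysis block so the lesion stays spectrally low-frequency);
* RF samples are the B-mode intensities halved with random signs, so
  `rf_to_bmode()` with offset 0 reproduces the constructed image bit-exactly;
* pixel-level ground-truth masks.

The benign/malignant dataset templates differ in the clinically motivated
directions — benign: small ellipses, mild drop (0.65–0.80), nearly
homogeneous; malignant: large rectangles, strong drop (0.15–0.25),
heterogeneous — with small per-sample jitter of layer brightness and
boundaries so no single constant separates the classes.

**What the generator does not emulate:** speckle spatial correlation from a
real point-spread function, depth-dependent attenuation and focusing,
shadowing/enhancement artifacts below lesions, irregular lesion boundaries,
and operator variability. Passing tests therefore demonstrate that the
pipeline is *correct and internally consistent* — the transform is exact,
the threshold is the Otsu optimum, the classifier learns separable spectral
classes, segmentation recovers planted lesions — not that the published
clinical performance transfers; that requires real annotated sonograms.

For segmentation validation the package provides
`phantom_with_block_lesion()`, which aligns the lesion rectangle to the
analysis grid. Block-level IoU against ground truth is only unambiguous when
lesion edges coincide with block boundaries: a half-covered boundary block
is a coin flip for any method, which would measure the phantom geometry, not
the segmenter. The general generator places lesions anywhere.

## Problem sizes used by the tests

The package's own validation uses: 50 random matrices up to 12×12 against
the direct quadruple-sum DCT; Parseval on 100 random matrices; Otsu versus
exhaustive search on 100 value sets (bimodal, uniform, skewed,
near-degenerate); 20 seeded lesion phantoms (1024×384, lesions of 6–20
blocks) plus lesion-free phantoms for segmentation; and 100 + 100 phantoms
for end-to-end classification with held-out evaluation. These sizes are the
package's choice of a thorough-but-quick default; nothing in the design
limits them.

## Known limitations

* The feature vector discards the singular *vectors*; two images with the
  same spectral energy profile but different layouts are indistinguishable
  to the classifier.
* Otsu assumes a two-class split of block statistics; multiple lesions of
  very different echogenicity may partially merge with the healthy class.
* The contrast gate's default (0.5) is tuned to the hypoechoic-lesion
  setting; hyperechoic pathology would need `min_contrast` reconsidered
  (and the healthy/suspicious direction is fixed: suspicious = low mean
  frequency).
* The network is intentionally small and the trainer batch-mode; very large
  datasets would call for minibatching, which SCG does not do.
* 16-bit raster output uses TIFF (PNG writing is 8-bit in the underlying
  library); 16-bit TIFF intensities truncate to integers on write.
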