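---
title: "Methods: enhancement, pooling and grading in fundusdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancement, pooling and grading in fundusdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusdr)
```

`fundusdr` implements a complete desk-scale pipeline for diabetic
retinopathy (DR) screening research: per-image contrast enhancement, image
quality assessment, class-balancing augmentation bookkeeping, a compact
residual grading network with a trainable sparse pooling layer, a linear
SVM head, and per-class evaluation. This vignette explains the models and
the choices behind them, in the order data flows through the pipeline.

## Contrast enhancement

### The incomplete-beta intensity transform

Low-contrast fundus photographs hide the small lesions (microaneurysms,
haemorrhages, exudates) that determine the DR grade. The enhancement
remaps each normalized intensity $v = g/255 \in [0,1]$ through the
regularized incomplete beta function

$$\Xi(v) \;=\; \frac{\int_0^v x^{c-1}(1-x)^{d-1}\,dx}
                    {\int_0^1 x^{c-1}(1-x)^{d-1}\,dx} \;=\; I_v(c, d),$$

and outputs $255\,I_v(c,d)$. The map is monotone for any $c, d > 0$, fixes
black and white, and spans the classical enhancement family: $c=d=1$ is
the identity, $c=d>1$ is a sigmoid mid-range stretch, $c>d$ brightens and
$c<d$ darkens. `beta_transform()` evaluates it through `stats::pbeta`,
which *is* the regularized incomplete beta function; a numerical
integration of the defining ratio is kept in the test suite as an
independent oracle.

### The enhancement fitness

The shape pair $(c, d)$ is chosen per image by maximizing a fitness that
rewards visible structure:

$$F \;=\; \log\bigl(\log \Sigma_\Psi\bigr)\;\cdot\;\frac{M_\Psi}{PQ}
  \;\cdot\; E \;\cdot\; Y,$$

where $\Sigma_\Psi$ is the summed gradient magnitude over Canny edge
pixels, $M_\Psi$ the edge-pixel count (normalized by the image area $PQ$),
$E$ the 256-bin Shannon entropy in bits, and $Y$ a band-limited local
contrast. The four factors combine multiplicatively; entropy is taken with
the conventional negative sum so that "more information" means a larger
value, and an image whose total edge strength does not exceed $e$ (so the
double log would be undefined) receives a large negative sentinel rather
than an exception. The contrast term follows the band-limited (Peli-style)
construction: the per-pixel ratio of a difference-of-Gaussians bandpass
($\sigma = 1$ minus $\sigma = 2$) to a Gaussian low-pass ($\sigma = 2$,
denominator floored at $10^{-6}$), averaged within non-overlapping blocks
(default 32 px) and summed over blocks. The Canny detector uses
$\sigma = 1$ smoothing and hysteresis thresholds at the 10th/30th
percentiles of the thinned gradient magnitudes, so it adapts to each
image's dynamic range; all of these constants are exposed as arguments.

### The artificial bee colony

`abc_optimize()` is a standard artificial bee colony over the rectangle
$(c, d) \in [0.5, 10]^2$: employed bees perturb one coordinate of their
food source toward a random partner, onlookers re-sample sources in
proportion to fitness, and sources stale for `scout_limit` trials are
re-scouted uniformly. Defaults (colony 20, limit 10, 30 cycles) follow
common ABC practice; the identity pair $(1,1)$ is always seeded into the
initial colony when the bounds allow, which gives the optimizer a no-harm
guarantee: the returned fitness can never fall below that of the untouched
image. The search is deterministic given its seed. Because each fitness
evaluation runs a Canny pass and two filter banks, the examples and tests
use smaller colonies (5–10 sources, 4–10 cycles) on 64–96 px images; the
defaults are sized for full 512 px working images.

One property the enhancement does *not* promise is an entropy increase: a
256-level lookup table cannot create histogram levels, and saturation can
merge them, so a stretched image may hold slightly less histogram entropy
than its degraded input even while edges, contrast and fitness improve.
The guarantee is on the fitness, not on any single factor.

For RGB fundus photographs the transform is applied to the green channel
by default — the channel with the highest vessel/lesion contrast in fundus
imaging — with the red/blue planes passed through; a luminance mode is
available.

## Image quality assessment

`quality_scores()` bundles five measures. Entropy and PSNR
($10\log_{10}(255^2/\mathrm{MSE})$, infinite for identical images) are the
standard definitions. SSIM uses the usual stabilizers
$A_1 = (0.01\cdot255)^2$, $A_2 = (0.03\cdot255)^2$ under an 11×11 Gaussian
window ($\sigma = 1.5$), averaged over pixels; a single-window global mode
is available. GMSD compares Prewitt gradient magnitudes through the
similarity $(2 g_r g_t + c)/(g_r^2 + g_t^2 + c)$ with $c = 170$ and
reports the population standard deviation of the similarity map. The
patch-based contrast index follows the PCQI construction — each 11×11
patch is split into mean intensity, signal strength and structure, scored
by a saturating $\tfrac{4}{\pi}\arctan$ contrast-gain term, a normalized
structure correlation, and an $\exp(-|\Delta\mu|/255)$ mean-shift penalty
— so identical images score exactly 1 and structure-preserving contrast
amplification scores above 1.

## Augmentation and splitting

Class balancing follows a count-arithmetic contract: a grade with $k \ge 1$
augmentation operations contributes exactly $k$ variants per original
(originals replaced), and a grade with $k = 0$ keeps its originals, i.e.
`augmented = original × max(k, 1)`. This rule reproduces every per-grade
cell of the published balancing tables this package's bookkeeping mirrors.
The train/test split is stratified per grade with the train share
`round(0.8 n)` rounded half away from zero — the only rounding rule
consistent with all published per-grade train counts (1598.4 → 1598 and
1389.6 → 1390 under one rule).

The image operators are rotation (0–180°, bilinear), horizontal shift,
horizontal flip, brightness and contrast (both ±20% by default).
Geometric operators fill uncovered pixels by mirror reflection rather than
black: black corners would inject spurious edges into the enhancement
fitness downstream.

## The grading network

### Trainable TOP-Q weighted pooling

Global average pooling summarizes a feature map with a single unimodal
statistic, which is a poor fit for fundus images whose activation
distributions are shaped by many small lesions. The pooling layer instead
forms $m$ candidate aggregates per channel — generalized means
$\bigl(\tfrac{1}{HW}\sum |x|^{p_k}\bigr)^{1/p_k}$ with exponents
$p = 1, 2, 4, 8$ by default, spanning the mean-to-max spectrum — and
combines them with learned weights. A shared "prediction" layer maps the
global-average channel descriptor through one hidden fully connected layer
to a latent code $c(\theta_p; Y)$; two linear maps then score each branch:

$$F_k = T^h_k\bigl(c(\theta_p;Y)\bigr) +
  \delta\,\varepsilon_k\,\log\bigl(1 + e^{T^m_k(c(\theta_p;Y))}\bigr),$$

with $\varepsilon_k$ standard normal during training (exploration noise,
scale $\delta = 0.1$) and dropped at evaluation so inference is
deterministic. The weights keep only the $Q$ largest scores: masked
entries are excluded from the softmax entirely, which is the exact
$-\infty$ masking and yields bit-exact zero weights; ties break toward the
lower branch index for determinism. With $m = 1$ the layer reduces exactly
to plain average pooling, which the tests assert bit-for-bit.

Whether the $m$ branches should index pooling statistics or spatial
regions is genuinely open; the statistic reading is implemented because it
composes cleanly with a shared global descriptor, and the spatial-region
alternative would change only the aggregate construction behind the same
scoring interface.

### Balance loss

Sparse gates collapse: whichever branches win early get trained and win
more. The counter-pressure is a loss on the coefficient of variation of
branch usage across a mini-batch, $L_s = 3\beta\,S(u)/M(u)$ with
$u_k = \sum_s w_k(Y_s)$ and $S, M$ the population standard deviation and
mean. It is zero exactly at uniform usage, and its gradient is added to
the branch-weight gradient during training. The total objective is
cross-entropy plus $L_s$ with unit weight on the cross-entropy; $\beta$
defaults to 0.1.

### Bounded piecewise-linear activation

All residual blocks and the pre-classifier dense layer use
$f(x) = x/2$ on $[-2, 2)$, saturating at $\pm 1$ outside — a bounded,
continuous, monotone replacement for ReLU ($f(2) = 1$, matching the left
limit, closes the half-open interval). Because the linear zone has slope
$\tfrac12$, activations shrink variance by $\tfrac14$ per layer; the
convolution and dense weights are therefore initialized with variance
$4/\mathrm{fan_{in}}$, the variance-preserving analogue of He
initialization for this slope. Without that correction the forward signal
(and gradient) decays geometrically with depth and training stalls.

### Architecture and training

The `"tiny"` preset — three stride-2 convolutions into residual blocks at
16/32/64 channels from a 64×64 input, the weighted pool, a 32-unit dense
layer, dropout 0.2 and a 5-way softmax — is the configuration all tests
and the acceptance script exercise; it trains on one CPU core in minutes.
A `"resnet50"` preset assembles the deep analogue at 225×225 for users
with the compute to train it; it shares every layer implementation but is
not exercised by the test suite. Config defaults follow the large-scale
recipe (batch 64, 1000 epochs, learning rate 0.001, kernel 3); the
desk-scale runs in tests and the acceptance script use batch 16, 15–30
epochs and learning rate 0.03 with momentum 0.9, chosen once from a
coarse sweep as the smallest setting that trains reliably at this scale.
All stochastic pieces — shuffling, dropout masks, pooling noise — draw
from one seeded stream, so training is bit-reproducible.

## The SVM head

The "improved SVM" head scores penultimate-layer features with per-class
linear maps $s_c = w_c \cdot p + b_c$ and predicts the argmax, ties
resolved toward the earlier grade in severity order. Training minimizes
the Crammer–Singer multiclass hinge $\max_{c \ne y}(0, 1 + s_c - s_y)$
plus an L2 penalty by full-batch subgradient descent over a fixed number
of epochs. The optimizer is deliberately minimal — scores, loss, weight
update — and deterministic given its seed; it drives the hinge loss to
zero on linearly separable data, which the tests check on toy sets and on
the network's own features.

## Synthetic data

The generator emulates what matters for testing, not photorealism: a
bright retina disc with radial falloff, an optic-disc-like bright region,
a dendritic dark vessel tree fanning out from it, and grade-dependent
lesions — small dark dots (microaneurysm-like), larger dark blobs
(haemorrhage-like) and bright clustered patches (exudate-like). Lesion
count ranges are monotone in grade and NoDR images carry none, so the
five classes are statistically separable and every image ships with a
ground-truth lesion ledger. `degrade_contrast()` provides the low-contrast
fixtures for the enhancement tests by blending toward the global mean and
adding Gaussian noise.

What passing tests on this data do **not** show: robustness to camera
variability, illumination gradients, label noise, or the much subtler
lesion appearance of real fundus photographs. The learnability checks
demonstrate that the network, pooling, loss and SVM plumbing can fit a
separable five-class image distribution — a correctness property of the
implementation, not a clinical claim.

## Numerical choices and edge cases

* Fitness: edge-strength sums $\le e$ → large negative sentinel, never an
  exception; low-pass denominators floored at $10^{-6}$.
* TOP-Q: masked softmax computed only over the kept set (exact zeros);
  ties by index.
* Balance loss: zero usage returns 0 with a warning; at exactly uniform
  usage the CV has a kink and the subgradient 0 is used.
* Metrics: PSNR of identical images is `Inf`; ratios with zero
  denominators in evaluation reports are 0 with an `undefined` flag.
* Split rounding: half away from zero; degenerate empty grades warn.
* Images: intensities validated to [0, 255]; quantization rounds then
  clamps.

## Problem sizes

The suite and acceptance script run at deliberately small scale: 64–96 px
synthetic images, 10-image enhancement batches, 200-image training runs of
15 epochs, and a 48 px two-epoch pipeline for the determinism check.
These sizes were chosen as the smallest at which every property under test
is stable.
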