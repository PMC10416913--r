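# fundusdr

Contrast enhancement and severity grading of retinal fundus images for
diabetic retinopathy (DR) screening research, in pure R.

Diabetic retinopathy is graded on a five-level scale — NoDR, Mild,
Moderate, Severe, PDR — from the lesions visible in fundus photographs:
microaneurysms, haemorrhages and exudates. `fundusdr` implements a
complete desk-scale pipeline for this problem, aimed at researchers who
want every stage testable, seeded and runnable on one CPU:

* **Enhancement** — the incomplete-beta intensity transform
  $g \mapsto 255\,I_{g/255}(c,d)$, with the shape pair $(c,d)$ selected
  per image by an artificial bee colony maximizing the fitness
  $F = \log(\log \Sigma_\Psi)\cdot(M_\Psi/PQ)\cdot E\cdot Y$
  (Canny edge strength and density, histogram entropy, band-limited local
  contrast). The identity transform is always seeded into the colony, so
  enhancement can never score below leaving the image alone.
* **Quality metrics** — entropy, PSNR, SSIM, GMSD and a patch-based
  contrast quality index.
* **Augmentation bookkeeping** — per-grade balancing with the
  `augmented = original × max(operations, 1)` rule, the five image
  operators (rotation, horizontal shift/flip, brightness, contrast), and
  stratified 80:20 splitting with round-half-away-from-zero train counts.
* **Grading network** — a residual CNN whose global pooling is a
  trainable TOP-Q weighted pool (m generalized-mean branches scored by a
  noisy gate; only the Q best keep nonzero softmax weight), a bounded
  piecewise-linear activation $f(x)=x/2$ on $[-2,2)$ saturating at
  $\pm1$, and a balance loss $3\beta\,S(u)/M(u)$ on branch usage.
  Forward and backward passes are hand-written and verified against
  finite differences.
* **Improved-SVM head** — per-class linear scoring of penultimate
  features, Crammer–Singer hinge training by subgradient descent, argmax
  prediction with severity-order tie-breaks.
* **Evaluation** — confusion matrices and one-vs-rest per-class
  accuracy / precision / recall / F1.
* **Synthetic data** — a seeded generator of graded schematic fundus
  images (retina disc, vessel tree, grade-dependent lesion counts) with a
  ground-truth lesion ledger, so the whole pipeline runs without any
  external dataset.

## Worked example

Generate a Severe-grade synthetic fundus image, wash out its contrast,
and let the bee colony pick a beta transform:

```r
library(fundusdr)

fx       <- generate_fundus("Severe", synth_config(size = 96), seed = 7)
degraded <- degrade_contrast(fx$image, factor = 0.4, noise_sd = 2, seed = 3)
res      <- enhance(degraded, abc_config(colony_size = 6, max_cycles = 5,
                                         seed = 11))
res$params
#> c = 5.114   d = 2.617
res$report
#> Enhancement fitness report
#>   edge intensity sum : 1.977e+04
#>   edge pixel count   : 1522
#>   entropy (bits)     : 3.2072
#>   local contrast     : 3.2908
#>   fitness            : 3.99441
```

The selected transform ($c \approx 5.1 > d \approx 2.6$) stretches the
upper mid-range, where the washed-out image's content sits; its fitness
3.99 compares to 0.92 for the degraded input — more and stronger edges,
higher local contrast. `quality_scores(reference, test)` reports the five
assessment measures for any image pair.

Training the tiny grading preset on synthetic data:

```r
ds    <- generate_dataset(40, synth_config(size = 64), seed = 5)
model <- build_model(model_config(depth = "tiny", batch_size = 16,
                                  learning_rate = 0.03, epochs = 15))
model <- train_network(model, unname(ds$images), ds$manifest$grade, seed = 2)
tail(model$history$accuracy, 1)    # ~0.99 training accuracy, chance = 0.2

feats <- extract_features(model, unname(ds$images))
svm   <- train_improved_svm(feats, ds$manifest$grade, seed = 1)
mean(svm_predict(feats, svm) == ds$manifest$grade)   # 1.0
```

A command-line interface covering every stage (`simulate`, `enhance`,
`metrics`, `augment`, `split`, `train`, `predict`, `svm-train`,
`evaluate`) ships as `inst/cli/fundusdr`.

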