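---
title: "Class-probability rendering: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-probability rendering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The procedure

ctrender implements a hybrid classifier for binary chest-CT slice diagnosis
(malignant pleural mesothelioma versus benign pleural disease) organized in
three steps:

1. **Region overlay.** A mask provider segments each slice; the masks are
   alpha-blended over the original grayscale image with opacity at most 0.5,
   so the segmented region and the tissue it belongs to stay visible
   together. The blended RGB image is what the classifier consumes.
2. **Class-based features.** A trainable image classifier with an appended
   logits head (one output per class) is trained on the overlaid training
   images. For every slice, the softmax of the logits gives a per-class
   probability vector `z = (F1, F2)`; these two numbers, not the wide
   penultimate representation, are the features carried forward. The raw
   pre-softmax logits are retained for the no-rendering ablation.
3. **Generative rendering, selection and classification.** Each sample's
   `z` is rendered into three small candidate images by a decoder MLP, a
   conditional GAN generator, and an index-conditioned NeRV-style network.
   A discriminative score `DS(m) = d(m, C_neg) / d(m, C_pos)` — Euclidean
   distance to the rival-class centroid over distance to the own-class
   centroid — picks the best candidate per sample; a small residual CNN
   embeds the selected images and a cubic-kernel SVM classifies them.

Evaluation is patient-grouped throughout: all slices of a patient stay on
one side of the 70/30 holdout and inside one fold of the k = 5
cross-validation, removing slice-level leakage. Reports carry per-class and
macro-averaged sensitivity, specificity, precision, F-score and accuracy
(`se = tp/(fn+tp)`, `sp = tn/(fp+tn)`, `pre = tp/(fp+tp)`,
`f = 2tp/(2tp+fn+fp)`, `acc = (tp+tn)/n`), ROC and precision-recall curves,
calibration bins, decision-curve analysis and bootstrap percentile
confidence intervals.

## The synthetic cohort and what it does (not) emulate

Real mesothelioma CT datasets are single-center and not redistributable, so
the package ships a phantom generator that reproduces the *structure* of
such a study: two balanced classes of patients (86 per class by default),
a clipped-Poisson number of slices per patient (mean 5.8, clipped to
[1, 12], optionally adjusted to an exact per-class total such as 504), and
a class signal that lives where the disease lives — the pleura. Each slice
is an elliptical thorax (body intensity 140) with two dark lung fields
(intensity 30) surrounded by a bright pleural rim (intensity 230). The rim
thickness is a baseline 3 px for the benign class and baseline +
`class_effect` px (default 4, with per-patient and per-slice jitter) plus
1-3 nodular bumps for the mesothelioma class. Additive Gaussian noise
(default SD 8 intensity units) and small per-slice lung shifts provide
within-patient variation. Patient demographics are sampled from the
marginal frequencies of the study population this structure mirrors
(76.2% asbestos exposure, 56.4% smoking, 59.3% chest pain, 66.9% weight
loss, stage and histology margins; age normal 56.8 +/- 14.6 years).

What the phantom does **not** emulate: CT physics (beam hardening, HU
calibration, reconstruction kernels), 3-D slice correlation beyond shared
patient parameters, anatomy other than body/lungs/rim, and any effect of
stage or histology on the image. Consequently, green tests demonstrate that
the pipeline's machinery is correct and that it recovers a pleural-rim
class signal it is pointed at; they say nothing about accuracy on clinical
data. The near-ceiling accuracies on a strongly separable phantom
(`class_effect = 6`) are expected and are a property of the phantom, not a
clinical claim.

## Design decisions in the open spots

**Training target of the renderers.** Nothing in the three renderer
architectures dictates what a "good" rendering of a probability vector is.
We train all three against a shared deterministic target encoding
`T(z)`: each class owns an unnormalized Gaussian bump (SD `H/6`) at a fixed
anchor — `(H/4, W/4)` and `(3H/4, 3W/4)` for two classes, in
half-pixel-centered coordinates so the two anchors are exactly symmetric
under 180-degree rotation — and the bump mixture is mapped linearly to
`[-1, 1]`. This choice makes every renderer testable against a closed-form
oracle, and preserves class information by construction (the map
`z -> T(z)` is injective). The decoder and NeRV renderers minimize mean
squared error to `T(z)`; the GAN trains a conditional discriminator on
(target, z) pairs with the generator loss `adversarial + 100 * MSE`, so
the adversarial game is anchored to the same target.

**Renderer training sets.** A well-trained backbone pushes the empirical
`z` towards the simplex corners, which under-determines the learned map in
the middle of the simplex. Renderer training therefore augments up to 200
subsampled empirical rows with a fixed 21-point grid along the simplex and
100 seeded uniform draws. The renderers are maps from the *whole*
probability simplex to images; fidelity is verified on a held-out uniform
z-grid (step 0.1) with tolerances 0.05 (decoder, NeRV) and 0.1 (GAN) mean
squared error.

**Discriminative-score orientation.** The score as printed,
`d(m, C_neg)/d(m, C_pos)`, is *large* for a candidate close to its own
class and far from the rival, yet a verbal reading of "lowest score is the
best representative" also circulates. We select by arg-max of
`d_neg/d_pos`, which matches the stated intent ("closest to its own class
center, farthest from the other"), and expose `orientation = "min_ratio"`
for the opposite convention. Ties break in the fixed order decoder, gan,
nerv. When a candidate coincides with its own centroid the score is the
capped sentinel `d_neg / 1e-12`. Centroids are fitted on training-split
candidates only and then applied to all samples — fitting them on
everything would leak test labels into selection.

**Backbone learning rate.** The study protocol this package mirrors
fine-tunes pretrained transformers at 1e-4 for 15 epochs. The bundled
reference CNN trains *from scratch*; at 1e-4 it is still near chance after
15 epochs, while 1e-3 reaches training accuracy above 0.99 on a separable
phantom within 5 epochs. `backbone_spec()` therefore defaults to 1e-3 with
the other protocol values unchanged (cross-entropy, Adam, batch 32,
constant learning rate, no weight decay, no early stopping, fixed seed).
The logits head is trained jointly with the body — it *is* the
classification head.

**Cross-validation placement.** The k = 5 cross-validation re-evaluates
the *classification stage*: the backbone, renderers and selection
centroids are fitted once on the holdout training split, then the residual
extractor and SVM are retrained per patient-grouped fold over all selected
images. Retraining the entire pipeline per fold would quintuple the cost
without changing what the CV measures here — the stability of the
classification stage. The residual-extractor features depend only on the
selection manifest and fold split, so scenarios that share them (SVM
versus logistic regression) reuse the same embedding.

**Bootstrap unit.** Confidence intervals resample evaluation *images*, not
patients. Within-patient slice correlation means image-level intervals are
somewhat anti-conservative; this is flagged here rather than hidden.

## Numerical choices

* Overlay blending: `round(alpha*color + (1-alpha)*base)` per channel,
  rounding half away from zero, clipped to [0, 255]; later masks overwrite
  earlier ones where they overlap; default `alpha = 0.5` sits exactly at
  the at-least-50%-transparency boundary.
* Toy segmenter: Otsu threshold on the normalized image, 8-connected
  components (4-connected labelling plus a diagonal union-find merge),
  area filter, components ordered largest first. Blank images yield an
  empty mask set, not an error.
* All networks run on an internal im2col/col2im + BLAS layer toolkit with
  Adam; gradients for every layer type are verified against finite
  differences in the test suite. Initialization is He-normal, seeded;
  every training loop derives its seed from the pipeline seed and the
  stage name, so stages are independently reproducible.
* Renderers: 32 x 32 output (rendered representations are deliberately
  low-resolution), decoder MLP 2-64-256-1024 (ReLU/ReLU/Tanh), GAN noise
  dimension 8 zeroed at inference, NeRV positional encoding with 6 bands
  and two stride-2 transposed-convolution upsampling blocks; Adam at 1e-3,
  at most 300 epochs.
* SVM: polynomial degree 3, `coef0 = 1`, cost 1, kernel scale
  `gamma = 1/(d * mean feature variance)` (the "Cubic"/"Auto" conventions
  of common classification-learner GUIs), one-vs-one, Platt-scaled
  probabilities. Logistic regression is ridge-regularized
  (`lambda = 1e-3`) so coefficients stay finite on separable data.
* Metrics with zero denominators report 0 with a warning rather than
  aborting a report; ROC ties cross thresholds simultaneously; AUC is
  trapezoidal (equal to the concordant-pair statistic); decision-curve
  thresholds of exactly 0 or 1 are excluded.

## Problem sizes used by the bundled verification runs

The package's own end-to-end verification (test suite and
`scripts/acceptance.R`) runs the full pipeline on an 86 + 86 patient
phantom cohort (1008 slices when the per-class total is pinned to 504,
128 px slices, `class_effect = 6`) with the backbone trained for 6 epochs
and renderer epochs 250/100/100 — sizes chosen so a complete run finishes
in minutes on a single CPU while leaving the signal chain intact. Unit
tests use smaller cohorts (32-64 px, 6-12 patients per class) because they
test contracts, not accuracy.

## Known limitations

* The phantom's separability ceiling makes absolute accuracies
  uninformative; only orderings (full model versus ablations) and
  contracts are meaningful test targets.
* Per-sample rendering consumes the full probability vector `z`; the
  per-scalar alternative (one image per feature *value*) is documented but
  not implemented — selection and the manifest operate per sample.
* Only the binary case is exercised end to end; `target_encoding()`
  generalizes to K anchors on a circle, but multi-class selection
  ("nearest rival" centroid search) is out of scope.
* External adapters (promptable foundation segmenter, pretrained
  transformer backbones, ImageNet residual networks) are specified by
  contract (`toy_provider()`-style provider functions, `backbone_spec()`
  names) but not bundled: they require weight downloads and are not part
  of the test surface.
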