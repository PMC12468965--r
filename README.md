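# ctrender

Hybrid classification of chest CT slices — malignant pleural mesothelioma
versus benign pleural disease — built around **class-probability
rendering**: instead of classifying wide deep-feature vectors, the pipeline
compresses each slice to its per-class probability vector, *renders* that
vector back into a small image with three generative techniques, picks the
most discriminative rendering per sample, and classifies the selected
images with a kernel SVM. The package is aimed at researchers who want a
fully testable, dependency-light reference implementation of this pipeline,
with a synthetic CT-phantom cohort standing in for clinical data that
cannot be redistributed.

## The method

For each slice, region masks from a pluggable segmenter are alpha-blended
over the image (opacity ≤ 0.5, so tissue stays visible). A trainable CNN
with an appended logits head produces class-based features: the softmax
probabilities `z = (F1, F2)`, where `F1` is the probability of
mesothelioma. Three renderers — a decoder MLP, a conditional GAN generator,
and an index-conditioned NeRV-style network — map `z` to 32 × 32 candidate
images. Per sample, the candidate maximizing the discriminative score

```
DS(m) = d(m, C_neg) / d(m, C_pos)        d = Euclidean distance
```

(distance to the rival-class centroid over distance to the own-class
centroid; centroids fitted on training-split candidates only) is kept, and
a small residual CNN plus a cubic-kernel SVM (degree 3, C = 1, kernel scale
auto, Platt probabilities) classifies the selected images.

Evaluation is patient-grouped (all slices of a patient stay on one side of
every split) with macro-averaged sensitivity, specificity, precision,
F-score and accuracy,

```
se = tp/(fn+tp)   sp = tn/(fp+tn)   pre = tp/(fp+tp)
f  = 2tp/(2tp+fn+fp)   acc = (tp+tn)/n
```

plus ROC/PR curves, calibration bins, decision-curve analysis and bootstrap
confidence intervals. An ablation grid re-runs the pipeline without
rendering (raw logits → SVM), with variance-threshold selection instead of
the discriminative score, and with logistic regression instead of the SVM.

## Worked example

A small synthetic cohort (12 + 12 patients, weak pleural-rim effect of
2 px over heavy noise) through the whole pipeline:

```r
library(ctrender)

cfg <- pipeline_config(
  cohort = cohort_config(n_patients_per_class = 12, class_effect = 2,
                         image_size = 64, noise_sd = 12, seed = 19),
  backbone = backbone_spec(epochs = 4, input_size = 64),
  renderer = list(H = 32, W = 32, decoder_epochs = 150, gan_epochs = 80,
                  nerv_epochs = 80),
  extractor = list(epochs = 3),
  seed = 23)
run <- run_pipeline(cfg)
run
#> <pipeline_run: 130 images, ds/residual_svm; holdout acc=0.9796, cv acc=0.9615>
tidy(run)
#> # A tibble: 2 × 8
#>   scheme      n   acc    se    sp   pre f_scr   auc
#>   <chr>   <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 holdout    49 0.980 0.98  0.98  0.98  0.980 1
#> 2 cv        130 0.962 0.963 0.963 0.962 0.962 0.994
table(run$manifest$selected_method)
#> decoder     gan    nerv
#>      95       4      31
run$reports$holdout$ci$acc[c("estimate", "lower", "upper")]
#> $estimate [1] 0.9795918
#> $lower    [1] 0.9183673
#> $upper    [1] 1
```

Reading the output: the 130-slice cohort is split 70/30 by *patient*; the
classification stage reaches 98% holdout and 96% pooled 5-fold accuracy;
the discriminative score mostly prefers the decoder rendering but switches
to the NeRV or GAN candidate for 35 samples; the bootstrap 95% interval on
holdout accuracy is [0.92, 1]. `autoplot(run$reports$holdout, "roc")` (or
`"pr"`, `"calibration"`, `"decision"`, `"confusion"`) draws the evaluation
curves, and `run_ablation_grid(cfg)` produces the 4-scenario × 2-scheme
comparison table.

A thin command-line front end lives in `inst/cli/ctrender.R`
(`cohort` / `run` / `ablate` subcommands over a YAML config).

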