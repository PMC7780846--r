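---
title: "Confounder-aware deep-learning analysis of sex differences in volumetric brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounder-aware deep-learning analysis of sex differences in volumetric brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sexdiffmri)
```

## The analysis problem

Sex differences in the pre-adolescent brain are subtle, bilateral, and
entangled with covariates that themselves differ between girls and boys —
most prominently pubertal stage (PDS), and to a lesser degree age and
socioeconomic status (SES). A classifier trained to predict sex from T1-weighted
MRI will happily exploit any of these confounders, so the spatial pattern it
learns cannot naively be read as "where the sexes differ".

`sexdiffmri` implements a pipeline that (i) trains a 3D convolutional network
end-to-end to predict sex from affinely registered, down-sampled brain
volumes; (ii) screens the network's learned *predictor variables* for
association with the confounders using a general linear model; (iii) builds
*confounder-free* saliency maps by restricting gradient back-propagation to
the unflagged predictors; and (iv) runs the downstream statistics a cohort
study reports: effect sizes, score–cognition correlations, partial mediation
with a permutation null, misclassification-by-puberty contingency tests,
per-stratum accuracy, ROI-feature baseline classifiers, and the DeLong
comparison of correlated ROC curves.

Because the motivating cohort data are access-restricted, the package ships a
synthetic-cohort generator that reproduces the *statistical structure* the
analysis assumes — two classes with localized intensity or shape effects,
confounders with their own spatial effects and realistic sex-linked
distributions, a cognitive mediator — with known ground truth, so every stage
is testable end to end.

## The model

Volumes enter on a cubic grid (64 voxels per edge at 2 mm spacing for
full-resolution data; the tests use 16 for tractability). Assuming bilateral
effects, each subject contributes two samples: the native volume and its
left–right mirror (`flip_to_pair()`), and the subject's prediction score is
the average over the two copies.

The network (`sexnet_config()`, `build_model()`) is a stack of convolutional
blocks — 3×3×3 kernels, zero padding, leaky rectifier (slope 0.01), 2×
max-pooling — followed by a fully connected classifier with a sigmoid output.
The *predictor variables* **P** are the flattened final feature map: one
predictor per spatial position and channel. This is deliberate: each
predictor then has a localized receptive field, so the confounder screen can
attribute predictors to brain regions and masking them out removes a
*regional* contribution to the saliency map. (A global-average-pooled
alternative was evaluated and rejected: with whole-brain pooling every
informative predictor mixes class and confounder signal, and the screen
flags essentially all of them.) With the default three blocks and 16 final
channels on a 16-voxel grid, M = 2³ × 16 = 128 predictors.

Training uses binary cross-entropy, Adam with decoupled weight decay
(default 10⁻³), mean-image subtraction (the mean training volume is stored
in the model and subtracted everywhere; being a constant offset it does not
change input gradients), seeded batch shuffling, and an automatic
re-initialization if a run ends at chance-level loss (a rare dead start;
`restarts`, `restart_loss`). A `label_smoothing` option exists but defaults
to 0: on strongly separable synthetic data, smoothing lets a single dominant
region satisfy the bounded-logit optimum alone, whereas the unsmoothed
trajectory approaches the max-margin direction, which spreads weight over
all informative regions — the behaviour the saliency analyses need.

Cross-validation (`crossvalidate()`) splits *subjects* (never hemisphere
copies) into k = 5 folds, stratified by sex. Training folds are balanced and
optionally inflated by rigid augmentation (`balance_augment()`: translations
up to 1 voxel, rotations up to 1° about each axis, trilinear resampling,
zero fill); the held-out fold is never augmented. Scores are binarized at
0.5 with ties assigned to the boy class, and `compute_metrics()` reports
balanced accuracy, TPR/TNR/FPR, and a tie-aware AUC.

## Confounder screening and saliency

For each predictor Pʲ an ordinary-least-squares fit of

Pʲ = β₀ + β₁ S + β₂ z_pds + β₃ z_age + β₄ z_ses

is computed across all hemisphere samples, and the three confounder
coefficients are tested two-sided. A predictor with any confounder p ≤ 0.05
is *confounded*. The threshold is deliberately lenient and uncorrected:
the screen is meant to be sensitive, accepting false-positive flags so that
the surviving pattern under-states rather than over-states sex differences.

Saliency (`compute_saliency()`) is the absolute input gradient of the
pre-sigmoid score, obtained by back-propagation with gradient flow restricted
to a chosen predictor subset (excluded predictors are stop-gradients;
screening happens after training, so no retraining is involved). The
absolute value is used so that averaging across subjects cannot cancel
opposite-signed contributions, and the pre-sigmoid output avoids the
vanishing derivative of saturated probabilities. Each per-subject map is the
bilateral average of the native map and the mirrored map of the flipped
volume, then min–max scaled to [0, 1] — importance values are only
comparable within one map, which is why scaling precedes cohort averaging.
A constant map scales to all zeros.

`cohort_pattern()` averages the scaled per-subject maps over the cohort with
the mask set to the unflagged (confounder-free) or flagged (confounded)
predictors; a confounder-specific pattern restricts the flagged set to
predictors whose smallest confounder p-value is achieved by that confounder.
The confounder-specific construction matters in practice: the pooled flagged
set always contains the α-level false-positive flags on genuine class
predictors, and those carry the strongest gradients, so the pooled pattern
can still be dominated by the class regions; attributing flags to their
confounder isolates the confounder's own spatial effect.
`roi_statistics()` aggregates per-subject maps over atlas ROIs, tests
girl-vs-boy differences with pooled two-sample t-tests, applies Bonferroni
correction over ROIs, and ranks ROIs by cohort-mean saliency.
`threshold_pattern()` binarizes a scaled pattern at τ = 0.1 by default.

## Downstream statistics

* `cohens_d()` uses the pooled SD with (n−1) weights — the convention that
  reproduces the published cognitive-battery effect sizes from their printed
  summaries.
* `two_sample_t()` is the pooled-variance t-test, usable directly from
  group summaries.
* `partial_mediation()` implements the three-condition scheme: (1) sex is
  associated with the mediator (pooled t); (2) the mediator is associated
  with the score S controlling for sex (t-test of the mediator coefficient
  in `lm(S ~ sex + mediator)`); (3) the sex–S correlation is significantly
  reduced when the mediator is partialled out. The condition-3 statistic is
  |r(sex, S)| − |partial r(sex, S | mediator)| with a permutation null
  obtained by permuting the mediator column;
  p = (1 + #{permuted ≥ observed}) / (1 + n_perm). The statistic and
  permutation scheme are this package's construction — the source analysis
  specifies only that the reduction p-value comes from a permutation test —
  and are stated here prominently for that reason.
* `misclassification_chi2()` forms, per sex, the PDS-level × group
  contingency table of always-correct vs always-wrong subjects (agreement
  across repeated cross-validation runs, `repeat_crossvalidate()`) and
  applies the Pearson χ² without continuity correction; adjacent levels are
  pooled with a warning if an expected cell falls below 1.
* `delong_test()` is a from-scratch implementation of the placement-value
  covariance estimator for two correlated ROC curves; its internal AUCs are
  identical to `compute_metrics()`. The test suite cross-checks it against
  an independent library implementation and a bootstrap oracle.
* `baseline_classifiers()` applies the identical subject-level CV protocol
  to logistic regression, an RBF SVM, and a random forest on tabular ROI
  features (`roi_features()`: per-ROI mean intensity plus the atlas
  voxel-count volume, the latter constant — hence dropped — when the atlas
  is exact, as in synthetic mode).

## The synthetic cohort

`generate_cohort()` draws a balanced cohort on a fixed spherical phantom:
bright "cortical" shell, mid-intensity interior, and six bilateral spherical
sub-regions, each pair sharing one atlas label and its own baseline
intensity. Covariates emulate a pre-adolescent cohort: age ≈ 9.9 ± 0.6
years in both sexes; PDS higher and more variable in girls (2.0 ± 1.0) than
boys (1.3 ± 0.6), clamped to [1, 5] — this builds in the sex–PDS
confounding; SES is an arbitrary continuous index (18 ± 67; the source
scale's distribution is not published beyond its summary, so SES is treated
generically). A latent class signal (2·(sex−½) + noise, SD 0.5) drives
mediator-type effects, and `generate_cognitive_scores()` draws the
seven-test battery from its per-sex summary specification, optionally adding
the within-sex part of the class signal to one test so that score carries
class variance beyond the binary label (the structure partial mediation
detects) without moving the per-sex means in expectation.

Effects are declared as `effect_spec(region, kind, driver, magnitude)`,
with magnitudes in units of the voxel-noise SD (default noise SD 0.2 against
a template of order 1 — a generous but not extreme contrast-to-noise
choice). `intensity_shift` adds a uniform offset over the region;
`volume_scale` is a volume-preserving shape cue implemented as a zero-mean
radial redistribution (inner core up, outer shell down, weighted to sum to
zero over the region, linear in the driver). The redistribution was chosen
over literal mask dilation because it is exactly linear in the driver and
guarantees that ROI-mean features carry no signal — the property the
deep-vs-ROI comparison isolates. Effects are bilateral by construction
because labels cover both mirror blobs.

What the generator does *not* emulate: anatomical shape variability,
registration error, scanner artifacts, intensity non-uniformity, or
cortical folding. Passing tests therefore demonstrate that the pipeline's
statistical machinery recovers known truth under its own assumptions, not
that the trained network transfers to real MRI.

## Numerical choices and degenerate inputs

* Ties at S = 0.5 binarize to boy (deterministic, documented).
* A constant saliency map min–max scales to all zeros.
* Constant (dead) predictors and predictors explained exactly by the design
  receive confounder p = 1 in the screen (float-noise coefficients below
  10⁻⁸ of the predictor's scale are never significant).
* Rigid transforms use trilinear interpolation with constant fill 0;
  shifts are continuous in [−1, 1] voxels, reading "within one voxel" as a
  bound; identity parameters return the input bit-exactly.
* Empty atlas ROIs are excluded from ROI statistics with a warning; strata
  missing either sex are excluded from per-stratum accuracy.
* All randomness is seeded: cohort generation, fold splits, initialization,
  shuffling, augmentation, permutations. Regenerating a cohort from the
  same seed is bit-identical.

## Problem sizes used by the test suite

The packaged experiments run on one CPU at deliberately reduced scale:
16³ grids, cohorts of 80–400 subjects, 10 training epochs, and 20 seeded
replicates for the saliency-recovery experiment (n = 400, sex effect of
magnitude 3 in one region, a PDS effect of magnitude 3 in another, PDS
confounded with sex). Saliency-attribution experiments use the single-block
localized extractor (`channels = c(8)`): on a 16-voxel grid the deeper
default's receptive fields span both effect regions, which blurs regional
attribution — at full 64³ resolution the same trade-off would be made at
greater depth. Mediation calibration uses 200–2000 permutations instead of
the full 10,000 of a production run; the permutation p-value is seeded and
bit-reproducible at any size.

## Known limitations

* The exact layer configuration of the original network is not public; the
  architecture here is a faithful small-scale member of the same family,
  and `sexnet_config()` keeps it swappable.
* Whether the original saliency used signed or absolute gradients, and the
  probability or the pre-sigmoid score, is unstated; this package uses the
  absolute gradient of the pre-sigmoid score for the reasons above.
* The GLM screen regresses predictors on the *probability* score S; when
  training drives S to saturation the screen loses the graded information in
  S, which slightly inflates confounder flags on class predictors. The
  lenient-threshold design accepts this direction of error.
* Head-size matching of real cohorts is out of scope beyond generic
  subsetting; the synthetic phantom has fixed head size by construction.
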