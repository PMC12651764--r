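---
title: "Scoring 3D cavity preparations from point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring 3D cavity preparations from point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In preclinical restorative dentistry, students prepare cavities in simulated
molars and examiners grade them against a structured rubric. prepscore
reimplements, as tested reusable code, a pipeline that automates this
assessment from 3D intraoral scans: an OBJ surface mesh of the prepared
tooth (and its neighbours) is converted to a fixed-size point cloud and
scored by a point-cloud regression network against a 9-item, 20-point
rubric, and the agreement between model and examiner scores is quantified
with a full method-comparison suite.

The package covers the complete loop: geometry I/O and preprocessing, the
rubric and its score arithmetic, a synthetic-preparation generator with
known ground truth, the network and its training procedure, the agreement
statistics, and pipeline entry points (`run_generate()`, `run_train()`,
`run_score()`, `run_evaluate()`, plus a thin shell dispatcher in
`inst/cli/prepscore.R`).

## The rubric

`rubric_criteria()` fixes the scheme: up to 9 points for complete caries
removal; 2 points each for buccal, lingual and gingival proximal clearance;
2 points for preserving tooth structure between the occlusal and proximal
cavities; 1 point for avoiding cusp weakening; 2 points for the absence of
undermined enamel; and a deduction of up to 2 points for minor (< 1 mm) or
up to 4 points for moderate (1-2 mm) iatrogenic damage to the adjacent
tooth. Simulated pulp exposure zeroes the total. The positive maxima sum to
20; totals are clamped below at 0 because a mark is not a signed quantity.

Reference scores are the average of two examiners (`average_examiners()`),
which is why half-point values are legal on examiner sheets and enforced
there only; model predictions are unconstrained reals within each
criterion's bounds. Labels live in JSON files with snake_case criterion
keys — the schema of record for this package — and are validated on read,
including a recomputation of the stored total.

## Preprocessing: deterministic sampling and pose normalization

`sample_point_cloud()` draws a fixed number of points (100,000 by default)
by area-weighted face selection and uniform barycentric placement. The
random stream is derived from a single seed *and* a hash of the mesh's
source label, so a batch of files yields the same clouds regardless of
processing order, and the same OBJ always produces bit-identical points.
Area-weighted sampling was chosen over blue-noise alternatives because it
is simple, exactly seedable, and its statistical contract (per-face counts
proportional to face areas) is directly testable.

`normalize_point_cloud()` translates the centroid to the origin and divides
by the maximum centroid-to-point distance (unit-sphere convention). Every
downstream score is therefore invariant to rigid translation and uniform
scaling of the scan — an invariance the test suite asserts end to end at
1e-5. Clouds round-trip through ascii PLY with their provenance (source
label, seed, normalization flag) in header comments.

## The network

`fit_prepnet()` trains a regression network of the PointNet family,
implemented directly in base R matrix algebra:

* shared per-point dense layers with batch normalization and ReLU
  (default widths 64-64-128-1024, the canonical trunk);
* a symmetric max-pooling over points into a global feature vector, which
  makes the output exactly invariant to point order;
* a fully connected head (default 512-256);
* nine outputs — the eight criteria plus a separately trained total — each
  passed through a logistic squashing affinely scaled to its rubric range.

Bounded outputs were chosen over linear outputs with clamping because
clamping kills the gradient at the bounds; the squashing keeps every
prediction inside its rubric range for *any* parameters, which the tests
assert. The ninth output exists because a jointly trained total need not
equal the sum of the predicted criteria; both totals are always reported
(`predict_sheet()` returns `total_head` and `criteria_total`).

Batch normalization is not cosmetic here. The max-pooled global features of
pose-normalized tooth scans vary across cases by roughly a percent of their
magnitude; without per-feature normalization the head faces a badly
conditioned problem and gradient training stalls. Per-point layers
normalize over all points of the batch, head layers over the batch, and
inference uses the running statistics — so a single cloud's prediction is a
pure function of that cloud, and permutation invariance is unaffected
(per-feature statistics are symmetric in the points). A learned input
alignment (T-Net) is deliberately absent: inputs are pose-normalized
upstream, and the config flag documents that decision.

## Training procedure

The loss is the mean absolute error in rubric points: the uniform-weighted
mean over the nine outputs of per-output mean absolute differences
(`mae_loss()`); a single case whose total is off by 1.8 points with exact
criteria contributes 0.2. Training runs in blocks of epochs (default two
blocks of 50) with a fresh Adam state (lr 1e-3, batch size 4) at each block
start; the optimizer, rate and batch size are package defaults exposed in
the configuration. Each epoch performs a seeded shuffle and minibatch
steps, then recomputes the MAE over the *full* training set — that
recomputed value, not the running minibatch average, is the training-loss
curve. A checkpoint is written every epoch; `restore_best()` returns the
checkpoint with the lowest training MAE, ties resolved to the earliest
epoch. There is no validation split: best-epoch selection uses training MAE
by design, mirroring the small-cohort setting the package emulates.
Training refuses any case tagged as test split (`prepscore_leakage` error).

Determinism is a platform contract: with fixed seeds and single-threaded
BLAS, repeated runs give identical curves; across platforms, identical
results to floating-point association are not guaranteed.

## The synthetic generator

The scan cohort the original pipeline was built on is not publicly
deposited, so `generate_cohort()` produces a synthetic stand-in: molar-like
crowns built as radially displaced subdivided icospheres (a height field
over the sphere, so every surface is closed and watertight with no boolean
solid operations). Cusps are smooth bumps on a ring 40 degrees off the
occlusal pole; the occlusal and mesial cavities are Gaussian depressions;
residual caries is a bump left on the cavity floor; undermined enamel a
shallow rim groove; a thin isthmus erodes the ridge between the cavities;
adjacent teeth are separate displaced spheres offset to realize the
requested proximal clearance, with iatrogenic damage as a depression on the
facing surface. Meshes are exactly deterministic in their parameters.

`scoring_map()` turns parameters into ground-truth scores with fixed,
config-visible cutoffs: clearance bands at 0.25/0.5 mm, isthmus bands at
0.5/1.0 mm, caries removal proportional to the fraction of carious material
removed (rounded to the half-point grid), enamel support proportional to
the undermined extent, cusp preservation from the cavity footprint against
the cusp ring, and a piecewise-linear damage deduction reaching -2 at 1 mm
and -4 at 2 mm. These geometric cutoffs are package constants standing in
for examiner judgement; the real study never defined geometry-to-score
rules, only point values, so any such map is a modelling choice.

Cohorts draw parameters from a skill-driven distribution: a latent operator
quality couples the fault magnitudes the way real student cohorts couple
them, so totals under the defaults span the full observed range (about 8 to
a perfect 20 in a 30-case cohort) with the 20/10 train/test split of the
emulated study design. Pulp exposure is off by default (the emulated score
tables contain none). A Gaussian vertex-jitter flag exists for scanner
noise but defaults to off.

What the generator does *not* emulate: real anatomical tooth morphology,
scanner artefacts (holes, seams, non-uniform triangulation), soft-tissue
remnants, or examiner disagreement beyond the averaging semantics. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline is
correct and learnable on geometry whose score-relevant features resemble
the real ones in kind and scale — not that the trained network would reach
the published accuracy on real scans. A learnability check guards the other
direction: a model-free geometric feature (`occlusal_depth_proxy()`, the
median crown radius in a 20-45 degree polar band minus the minimum radius
in a 15 degree cone) must rank-correlate with the mapped caries score above
0.5 on a default cohort, ensuring the synthetic task is signal, not noise.

## Agreement statistics

`agreement_report()` compares predicted and reference totals with MAE,
RMSE, Pearson r, Spearman rho, Lin's concordance correlation, Bland-Altman
bias with 95% limits of agreement, and within-threshold accuracy;
`icc_2_1()` covers inter-rater reliability. Conventions, all of which
matter at n = 10-20:

* differences are **predicted − reference** throughout;
* Lin's coefficient uses population (1/n) moments, the original
  convention, with `population = FALSE` available; its accuracy component
  is `Cb = rho_c / r`;
* Bland-Altman uses the sample (n−1) standard deviation and 1.96;
* Spearman is Pearson on mid-ranks (tie-corrected), which matters because
  rubric totals tie often;
* ICC(2,1) is the two-way random-effects, absolute-agreement, single-rater
  form computed from the two-way mean squares;
* `pct_within()` compares with ≤ plus a 1e-9 absolute guard, so a
  difference of exactly 1.0 counts as within ±1.

Every statistic is tested against an independent brute-force implementation
(including an ANOVA route for the ICC) at 1e-9 on random instances.

The package ships the published per-case score tables of the pilot study it
reimplements (`pilot_score_table()`), rounded to one decimal as printed.
Statistics recomputed from those rounded tables legitimately differ from
the study's headline values, which were computed on unrounded scores — the
recomputed test-set bias, for instance, differs from the published one
while the within-±1/±2 accuracies match exactly. Two printed cells are
internally inconsistent (an occlusal-preservation value above its 1-point
maximum; one case whose printed criteria do not sum to its printed total);
the fixtures preserve them verbatim rather than silently reconciling, and
sheet validation would reject them by design.

## Numerical choices and degenerate inputs

* Sheet bounds are checked with a 1e-9 slack; stored totals must agree with
  recomputed totals within 1e-6.
* Correlation-type statistics raise a named `prepscore_degenerate` error on
  zero-variance input rather than returning NaN; an all-equal rater matrix
  does the same for the ICC.
* Max-pool argmax ties break to the first point; best-epoch ties to the
  earliest epoch; half-point rounding uses round-half-to-even.
* Zero-area faces are dropped on OBJ read (with a message); a mesh with no
  remaining faces, an out-of-range face index, and a missing file each
  raise a distinct error class.
* Cavity depths reaching the crown radius are rejected as self-intersecting
  at parameter construction.

## Problem sizes

The package's tests and examples run at desk scale on one CPU: networks
with a 32-64-128 trunk and 64-32 head on 2048-point clouds, 30-case
cohorts, and 100-epoch runs (two blocks of 50) — the same shapes as the
emulated study design, with the cloud resolution and widths reduced from
production scale. Inference-scale preprocessing (100,000 points) is
exercised directly in the preprocessing tests, where it is cheap; full
production-width training (1024-wide trunk on 100,000-point clouds) is a
matter of configuration, not code.

## Known limitations

* The synthetic geometry is a stylized stand-in; criterion-level accuracy
  on real scans cannot be inferred from it.
* Training MAE is the model-selection signal (no validation split), so the
  reported best epoch is optimistically biased — a deliberate mirror of the
  emulated workflow.
* Generalization at cohort size 30 is noisy; the package's own acceptance
  checks therefore assert rank-level generalization (positive Spearman,
  3-seed median) rather than point accuracy.
* The checkpoint format is R's native serialization, one file per epoch;
  it is a working format, not an interchange format.
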