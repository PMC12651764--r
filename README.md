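# prepscore

Automated rubric scoring of 3D dental cavity preparations from surface
scans.

In preclinical restorative dentistry, students prepare two-surface cavities
(one occlusal, one mesial) in simulated lower first molars, and examiners
grade each preparation against a structured 20-point rubric. `prepscore`
reimplements a clinician-built pipeline that automates that assessment: a
scanned preparation in Wavefront OBJ format is converted to a deterministic
100,000-point cloud, pose-normalized to the unit sphere, and scored by a
point-cloud regression network of the PointNet family. Because the original
scan cohort is not publicly deposited, the package also ships a parametric
generator of synthetic molar-like preparations whose geometry maps
deterministically to ground-truth scores, plus the full method-agreement
suite used to compare model and examiner scoring.

## The rubric

Nine items, 20 points: caries removal (0–9), buccal/lingual/gingival
proximal clearance (0–2 each), preservation of structure between the
cavities (0–2), occlusal (cusp) preservation (0–1), absence of undermined
enamel (0–2), a deduction for iatrogenic damage to the adjacent tooth
(0 to −4: up to −2 below 1 mm, to −4 at 1–2 mm), and a pulp-exposure flag
that zeroes the total. Reference scores are the average of two examiners,
so half points occur. Totals are clamped at 0 and never exceed 20.

## The model

For a cloud of points $x_1,\dots,x_n \in \mathbb{R}^3$, shared per-point
layers with batch normalization and ReLU produce features
$h(x_i)$; a symmetric max-pool $g = \max_i h(x_i)$ yields a global
descriptor (hence exact invariance to point order); a fully connected head
maps $g$ to nine outputs — the eight criteria and a jointly trained
total — each squashed through a logistic function affinely scaled to its
rubric range, so every prediction respects its bounds by construction.
Training minimizes the mean absolute error in rubric points (uniform mean
over the nine outputs) with Adam, in two 50-epoch blocks with a fresh
optimizer per block, a checkpoint every epoch, and restoration of the
epoch with the lowest training MAE. The network, backpropagation (including
through the normalization layers) and optimizer are implemented in base R
matrix algebra; no deep-learning framework is required.

Agreement between predicted and reference totals is summarized with MAE,
RMSE, Pearson *r*, tie-corrected Spearman ρ, Lin's concordance ρc with its
accuracy component Cb, Bland–Altman bias with 95% limits of agreement,
ICC(2,1) for rater reliability, and the percentage of cases within ±1 and
±2 points.

## Worked example

Score agreement on the per-case score tables of the pilot study this
package reimplements (shipped as fixtures, rounded to one decimal as
printed):

```r
library(prepscore)
p <- pilot_total_pairs("test")   # 10 held-out cases
agreement_report(p)
#> Agreement over 10 cases (predicted vs reference totals)
#>   MAE 0.950  RMSE 1.141  r 0.941  rho 0.908
#>   Lin rho_c 0.839 (Cb 0.891)  bias +0.230  LoA [-2.078, 2.538]
#>   within +/-1 points: 50.0%
#>   within +/-2 points: 100.0%
```

Half of the predictions sit within ±1 rubric point of the examiner average
and all within ±2. (The pilot's published headline statistics were computed
on unrounded scores, so values recomputed from the rounded tables — e.g.
the bias — differ slightly; the within-threshold accuracies match exactly.)

End-to-end on a synthetic cohort (30 cases, 20 train / 10 test):

```r
dir <- file.path(tempdir(), "cohort")
run_generate(n = 30, seed = 1, out_dir = dir)      # OBJ + JSON pairs + manifest
ck <- file.path(tempdir(), "ckpt")
fit <- run_train(dir, ck, run_config())            # two 50-epoch blocks
fit
#> Point-cloud rubric scoring network (prepnet)
#>   20 training cases, 2048 points/cloud, 21,513 parameters
#>   epochs: 50+50 (blocks)  best epoch: 90  best training MAE: 0.511
```

and score a single scan exactly as an end user would:

```r
obj <- list.files(file.path(dir, "test"), pattern = "obj$", full.names = TRUE)[1]
run_score(obj, file.path(ck, "best.rds"))
#> {
#>   "case_id": "case_009.obj",
#>   "clearance_buccal": 0.242031,
#>   "clearance_lingual": 0.201779,
#>   "clearance_gingival": 1.676503,
#>   "preservation_between": 0.810792,
#>   "occlusal_preservation": 0.996234,
#>   "caries_removal": 8.075062,
#>   "no_undermined_enamel": 1.902789,
#>   "adjacent_damage": -0.047421,
#>   "criteria_total": 13.857768,
#>   "total": 13.376994
#> }
```

Both the sum of predicted criteria (`criteria_total`) and the network's
direct total output (`total`) are reported; they need not coincide. The
same OBJ and checkpoint always produce byte-identical output, and a
translated or uniformly rescaled copy of the scan scores identically.
Generalization at cohort size 30 is noisy — single runs of
`run_evaluate()` on 10 unseen synthetic cases can swing widely — so the
package's acceptance checks assert rank-level generalization as a
three-seed median rather than point accuracy on one draw.

A thin shell dispatcher wraps the same functions:

```sh
Rscript inst/cli/prepscore.R generate --n 30 --seed 1 --out cohort/
Rscript inst/cli/prepscore.R train --data cohort/ --checkpoints ckpt/
Rscript inst/cli/prepscore.R score --obj cohort/test/case_009.obj --checkpoint ckpt/best.rds
Rscript inst/cli/prepscore.R evaluate --data cohort/ --checkpoint ckpt/best.rds --out eval/
```

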