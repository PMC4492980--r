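# ctnorm — CT-guided spatial normalization for dopamine-transporter PET

Quantifying striatal dopamine-transporter binding from FP-CIT PET needs each
subject's PET image warped into a standard space where a striatal
volume-of-interest (VOI) template applies.  Normalizing PET directly to a
ligand-specific PET template fails in Parkinson's disease (PD): posterior
putaminal uptake is lost while the anatomy is intact, so the warp stretches
the bright anterior putamen backwards to fill the defect and the measured
SUVR (`SUVR = SUV_target / SUV_cerebellum`) is overestimated.  Structural
guidance avoids this, and when MR is unavailable the CT acquired by every
PET/CT scanner can guide the normalization instead — after one of two
preparations:

* **itCT**: a continuous, monotone piecewise intensity map that compresses
  the skull–brain contrast — `v ≤ −100 ↦ v + 1000`;
  `−100 < v ≤ 100 ↦ 900 + (v + 100)·(3100 − 900)/200`; `v > 100 ↦ v + 3000`;
* **ssCT**: probabilistic-atlas skull-stripping (MAP tissue segmentation
  with cohort tissue priors and a short EM loop, then masking to the brain
  segment).

The package is for imaging methodologists who want these routes — plus MR-
and PET-guided routes on the same registration engine (rigid NMI/SSD,
12-DOF affine, low-frequency DCT warps with bending-energy regularization),
template/VOI construction, SUVR/bias quantification and the full evaluation
battery (group t-tests, ROC AUC, severity regression, mean/SD images,
worse-side flipping, permutation-corrected voxelwise t-maps) — in a fully
testable form.  Because no real scans are redistributable, a seeded
synthetic head-phantom generator supplies cohorts with exactly known
anatomy, transforms, uptake and severity; every headline claim is then a
measurable quantity against ground truth.

## Worked example

```r
library(ctnorm)
cfg <- run_config(n_hc = 4L, n_pd = 3L, seed = 1L,
                  phantom = phantom_params(grid_n = 48, spacing = 4),
                  routes = c("itCT", "PET"), regions = c("caudate", "putamen"),
                  out_dir = "readme_run")
res <- run_study(cfg)
writeLines(readLines(res$report_path))
```

About 90 seconds on one CPU, printing:

```
| method | region | HC SUVR | PD SUVR | HC bias % | PD bias % | t | AUC |
|---|---|---|---|---|---|---|---|
| itCT | caudate | 5.90 ± 0.72 | 4.21 ± 0.28 | -3.8 | -10.7 | 3.77 | 1.000 |
| itCT | putamen | 7.27 ± 0.44 | 4.04 ± 0.54 | 0.5 | 0.5 | 8.82 | 1.000 |
| PET | caudate | 6.02 ± 0.58 | 4.80 ± 0.38 | -1.6 | 1.8 | 3.11 | 1.000 |
| PET | putamen | 7.37 ± 0.20 | 5.26 ± 0.35 | 2.0 | 31.7 | 10.11 | 1.000 |
| TRUTH | caudate | 6.13 ± 0.76 | 4.73 ± 0.51 | 0.0 | 0.0 | 2.73 | 0.917 |
| TRUTH | putamen | 7.23 ± 0.31 | 4.02 ± 0.55 | 0.0 | 0.0 | 9.89 | 1.000 |
```

Read it row-wise: `TRUTH` is each subject's own ground-truth VOI on the
native PET (SUVR in healthy controls ≈ 7.2, in patients ≈ 4.0 — the
partial-volume-diluted image of the generative 8.9 vs 4.6 putaminal
uptake).  The itCT-guided route reproduces truth almost exactly in the
putamen (bias +0.5% in both groups), while the PET-guided route
overestimates putaminal SUVR by **+31.7% in patients** but only +2.0% in
controls — the anterior-stretch artifact, appearing only where the
posterior deficit exists.  Both routes separate the groups (t, AUC), but
the PET route's patient values are inflated toward normal.

Individual stages are exposed as ordinary functions (`generate_subject`,
`intensity_transform`, `make_ssct`, `rigid_register`/`affine_register`/
`nonlinear_register`, `apply_transform`, `build_template_set`,
`normalize_pet`, `measure_suv`, `roc_auc`, `voxelwise_ttest`, ...), and a
thin CLI wraps cohort generation and the end-to-end study:

```sh
Rscript inst/cli/ctnorm run --n-hc 8 --n-pd 6 --seed 1 --out run_dir
```

## Layout

```
R/                 phantom, ctprep, transforms/register, templates,
                   quantify, evaluate, run_study
tests/testthat/    unit + property tests and end-to-end acceptance checks
vignettes/         methods vignette: model, assumptions, design choices
inst/cli/ctnorm    command-line entry point
scripts/acceptance.R
```
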