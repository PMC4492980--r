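---
title: "CT-guided spatial normalization of dopamine-transporter PET: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-guided spatial normalization of dopamine-transporter PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantifying striatal dopamine-transporter binding from FP-CIT PET requires a
volume-of-interest (VOI) template applied in a standard anatomical space, and
therefore a spatial normalization of each subject's PET image into that
space.  Normalizing the PET image directly to a ligand-specific PET template
is attractive (no second modality needed) but fails in a characteristic way
in Parkinson's disease: uptake in the posterior putamen is severely reduced
while the structure itself is intact, so an intensity-driven warp stretches
the still-bright anterior putamen posteriorly to "fill" the defect.  The
template putamen VOI then samples anterior-level uptake and the measured
specific-to-cerebellar uptake ratio (SUVR) is overestimated — precisely in
the patients one wants to measure.  Structural guidance avoids this: an MR
image, or — when MR is unavailable — the CT that every PET/CT scanner
acquires anyway.  This package implements and evaluates the two CT
preparation routes that make head CT usable for registration:

* **itCT** — a piecewise intensity transformation that compresses the huge
  skull-air-brain contrast: values at or below −100 HU are offset by +1000,
  values above +100 HU by +3000, and the (−100, 100] soft-tissue window is
  linearly rescaled onto (900, 3100].  The map is continuous and monotone,
  so tissue ordering is preserved while the skull no longer dominates the
  registration cost.
* **ssCT** — probabilistic-atlas skull-stripping: the CT is made
  non-negative, affinely aligned to a whole-CT template, scalp-stripped with
  an inversely-warped template mask, segmented into skull/brain/CSF by a
  per-voxel maximum-a-posteriori rule (class priors from cohort-average
  tissue maps, per-class Gaussian likelihoods re-estimated by a short EM
  loop, ties broken skull > brain > CSF), and masked to the brain segment.

Both routes, plus an MR-guided route and the PET-template route, run on one
shared registration engine, and the package quantifies how each route biases
striatal SUVR against ground truth.

## Synthetic cohorts as ground truth

Real scans for this design are not redistributable, and no deposited data
exist; validation therefore runs on a seeded synthetic head phantom with
exactly known anatomy, transforms and uptake.  The canonical head is a set
of nested ellipsoids (scalp, skull shell, CSF shell, brain parenchyma,
paired ventricles) with analytically defined caudate, putamen and cerebellum
— analytic shapes give exact ground-truth label volumes.  Per subject, the
canonical anatomy is carried through a random affine (rotations up to ±6°,
translations ±5 mm, scales ±5%) composed with a smooth random cosine-basis
warp (coefficient SD 0.8 mm, 3 components per axis), and three images are
rendered in subject space:

* **CT** in Hounsfield units (air −1000, CSF 10, brain/soft tissue 30-40,
  skull 1000) with 5 HU additive Gaussian noise, the soft-tissue noise level
  of a standard-dose (120 kV / 180 mAs) brain CT;
* **PET** with nonspecific background 1.0, cerebellum 1.0 (the SUVR
  reference), CSF 0.3, and subject-level striatal uptake drawn from the
  emulated cohort's moments: healthy-control (HC) caudate 7.2 ± 1.4 and
  putamen 8.9 ± 1.3; patient (PD) caudate 5.2 ± 1.5 and whole putamen
  4.6 ± 1.1.  PD putamina carry an anterior-to-posterior linear deficit of
  amplitude 3.2 — over the posterior half of a solid ellipsoid a linear
  profile averages to `level − 3g/8`, so the population posterior-putamen
  mean is calibrated to 3.4 — plus a ±7.5% left-right asymmetry tied to the
  clinically worse side (which is contralateral to the more affected
  striatum).  The image is blurred with a 6 mm FWHM Gaussian point-spread
  function, under which partial-volume behaviour emerges without scanner
  modeling, and 0.05 SUV noise is added.  The gradient shape (linear vs
  step) is exposed in configuration because intra-striatal uptake texture is
  not well characterized; linear is the default.
* an **MR-like** volume (relabeled tissue contrast, no bias field —
  inhomogeneity correction is out of scope).

A synthetic severity score `severity = 51 − 5 × (putaminal uptake) + N(0,
5.9)`, floored at zero, gives PD severities of about 28 ± 8 and makes the
severity-against-SUVR regression recoverable by construction.  What the
phantom deliberately does **not** model: cortical folding, OSEM
reconstruction noise texture, attenuation/scatter physics, metal artifacts,
head motion.  Passing tests therefore demonstrate correctness of the
pipeline's geometry, statistics and failure modes — not clinical performance
on real scans.

## The registration engine

All transforms are world-to-world (mm, RAS+) maps in the pull-back
convention: registering `moving` to `fixed` returns the map from fixed-space
points into the moving space, which is directly what resampling needs.

* **Rigid (6-DOF)**: multi-resolution Nelder-Mead with center-of-mass
  initialization; normalized mutual information (32-bin joint histogram) for
  cross-modality pairs, SSD on standardized volumes otherwise.
* **Affine (12-DOF)**: Levenberg-damped Gauss-Newton on SSD over
  translations, rotations, log-scales and shears, at 8 then 4 mm smoothing.
* **Nonlinear**: displacement fields synthesized from a separable 3-D DCT
  basis, 8 components per axis by default — at the 192 mm head field of view
  this is the conventional 25 mm cutoff of the classic basis-function
  normalization family — estimated by Gauss-Newton on standardized SSD with
  a bending-energy penalty (coefficients weighted by the 4th power of their
  spatial frequency, weight `lambda = 5`).  Bending rather than membrane
  weighting matters on CT: the brain interior of a CT is nearly
  contrast-free, and first-order regularization lets mid-frequency
  components drift on noise, while the curvature penalty pins them without
  stiffening the large-scale stretch that registration genuinely needs.
  The constant basis term is excluded — translations belong to the affine
  stage, and bending energy cannot see them.
* The nonlinear stage runs entirely at 8 mm smoothness with
  every-3rd-voxel sampling, the working smoothness conventional for
  template normalization.  A finer precision schedule (`basis_k = 6`,
  levels 8/4/2 mm) is exposed for same-modality warp recovery, where it
  reaches sub-millimeter mean residuals; the 8 mm default is the one used
  for cohort normalization, where matching at scanner resolution would
  chase noise.
* Deformation fields invert by per-point fixed-point iteration (stop at
  mean residual < 0.1 mm or 50 sweeps); affines invert exactly; compositions
  invert part-wise.  Degenerate inputs (constant images, singular affines,
  empty masks) raise errors rather than returning silently wrong results.

Registration contains no randomness: given identical inputs it returns
identical transforms, and reported final costs never exceed the cost of the
initialization (the engine falls back to the initialization if a level
fails to improve it).

## Templates and VOIs

Cohort templates (whole-CT, itCT, ssCT, MR, ligand-specific PET; tissue
probability maps; the scalp-stripping mask) are voxelwise averages of
control subjects brought into template space with their gold-standard
normalization parameters — the phantom analogue of building templates with
MR-guided parameters, as the original construction does.  Regional
probability maps thresholded at 0.8 (inclusive — the boundary rule is a
design choice, stated rather than implied) give the VOI template; where
several regions pass, the highest probability wins with ties broken in a
fixed region order.  The striatal VOI is further parcellated by an
explicitly simplified geometric scheme: ventral striatum below the axial
plane one voxel under the combined caudate-putamen centroid, then
anterior/posterior halves of each nucleus at the coronal plane through its
centroid.  The subregions partition the parent labels exactly; the scheme
stands in for atlas-based subregional templates, which are not reproducible
from the published description.

## Quantification and evaluation

For each subject and route, the PET is resampled to template space through
the route's composed transform and regional SUV is the arithmetic mean
under the VOI label; `SUVR = SUV_target / SUV_cerebellum`;
`bias% = 100 × (SUVR_route − SUVR_truth) / SUVR_truth`, with truth measured
by the subject's own ground-truth labels on the native PET (the phantom
analogue of subject-specific anatomical VOIs).  PET is not rigidly
coregistered to CT by default — PET/CT scanner geometry co-aligns them — but
an NMI rigid step is available by flag.  `side = "both"` is the mean of the
two unilateral means, and worse/better sides resolve contralaterally to the
recorded clinically worse side.

The statistics layer wraps the evaluation battery: pooled-variance two-sample
t-tests (Welch by flag; the pooled Student form is what legacy analysis
software defaults to), ROC AUC as the Mann-Whitney probability with ties at
one half and an explicit direction flag (lower SUVR indicates disease),
ordinary least-squares regression, mirror-flipping so the more-affected
hemisphere lies left, voxelwise mean/SD images, and a voxelwise two-sample
t-map with max-T permutation family-wise correction (default 1000 seeded
relabelings).  Permutation correction replaces random-field theory
deliberately: it is assumption-light, exact under exchangeability, and
testable by null calibration at desk scale.

## Numerical and scale choices

The default phantom grid is 64³ at 3 mm isovoxel (192 mm field of view) —
the scanner's 512 × 512 × 110 at 0.668 × 0.668 × 2 mm is configuration-only.
Test fixtures use 48³ at 4 mm or 32³ at 6 mm over the same field of view so
the head is never clipped.  End-to-end checks use cohorts of 6-12 subjects
per group; at these sizes the full four-route study runs in minutes on one
CPU, and the headline contrast (PET-route putaminal overestimation in PD
exceeding 30% while both CT routes stay within a few percent of truth)
reproduces with the default seed.  Regional means, t-tests, AUCs and
regressions are sample-size independent in expectation, so the scaled-down
cohorts change power, not direction.

## Known limitations

* CT interior contrast in the phantom (ventricles, 20 HU against brain) is
  the only interior constraint for CT-guided warps, as in real CT; the
  nonlinear stage therefore adds little over the affine inside the brain
  and the CT routes' residual bias is boundary-driven.
* The ssCT segmentation EM uses fixed 3 iterations and Gaussian class
  likelihoods; pathological intensity distributions (metal artifacts,
  hemorrhage) are out of scope.
* The identical canonical anatomy across subjects makes probabilistic maps
  nearly binary, so the 0.8 VOI threshold erodes less than it would across
  genuinely variable anatomy; template-VOI versus subject-VOI geometric
  offsets seen with real cohorts are correspondingly absent.
* Field inversion is fixed-point, valid for the moderate warps generated
  and estimated here; it is not a diffeomorphic guarantee.
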