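---
title: "Automated RECIST 1.1 response assessment from 3D lesion masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated RECIST 1.1 response assessment from 3D lesion masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recistmask)
```

## The problem

Response Evaluation Criteria in Solid Tumors (RECIST 1.1) reduces a pair of
imaging examinations — a baseline and a post-treatment follow-up — to one of
four categories: complete response (CR), partial response (PR), stable
disease (SD) or progressive disease (PD). The reduction is driven by a small
set of size rules: lesions are *measurable* from 10 mm longest axial
diameter; up to five of the largest measurable lesions become *target
lesions*; the sum of their longest diameters (SLD) is compared between
timepoints; a decrease of at least 30% is PR, an increase of at least 20%
(and at least 5 mm) is PD, disappearance is CR, anything else is SD.

When lesions come as 3D segmentation masks — for instance liver metastases
segmented on diffusion-weighted MRI (DWI), where metastases are markedly
hyperintense — the whole assessment can be computed mechanically. This
package implements that rule-based program, plus the instrumentation that an
evaluation of such a pipeline needs: segmentation-quality metrics,
inter-rater agreement statistics, a synthetic phantom generator with
analytic ground truth, and a small two-stage segmentation network for
desk-scale experiments.

## From mask to measurement

All geometry runs on a `label_volume`: a 3D integer array with a physical
voxel spacing in mm and a designated through-plane (slice) axis. Abdominal
DWI stacks are strongly anisotropic — roughly 1.5 mm in plane and 4–5 mm
between slices — so the slice axis is inferred as the largest-spacing axis
unless overridden. The physical position of voxel `(i, j, k)` is
`(i-1, j-1, k-1) * spacing`; every distance in the package is between voxel
centers under this convention. No resampling or registration is attempted:
masks that are compared must share a grid, and `check_geometry_match()`
enforces it.

`extract_lesions()` intersects the tumour mask with the liver mask (lesions
segmented outside the organ are discarded, mirroring cascaded
organ-then-lesion segmentation), partitions the remaining foreground into
connected components, and measures each component. The connectivity default
is 26 (faces, edges and corners), the usual convention for 3D lesion
labelling; 6 and 18 are available because the choice is occasionally
material — two lesions touching at a single corner voxel are one component
at 26-connectivity and two at 6.

The RECIST-relevant measurement is the **longest axial diameter**: for each
axial slice intersecting the lesion, the maximum pairwise Euclidean distance
between in-plane voxel centers (the 2D Feret diameter over centers), and the
maximum of that over slices. This mimics the in-plane caliper measurement a
reader takes on an axial image. Three consequences are worth stating:

* a single-voxel slice contributes 0 — the convention treats a point as
  having no extent;
* measuring center-to-center rather than across pixel footprints
  underestimates a solid's true diameter by up to about one in-plane voxel;
  on the default 1.5 mm grid, digitized spheres of 10–40 mm are recovered
  within 1 mm (checked against an all-pairs brute-force oracle in the test
  suite);
* holes inside a lesion are not filled; the program measures what the mask
  contains, which matches annotation practice of including necrotic areas
  in the mask rather than leaving cavities.

For slices with more than 32 in-plane points the pairwise maximum is taken
over the convex hull first; this is a pure optimization and the tests assert
exact equality with the brute-force computation.

## The rule engine

`recist_config()` collects the tunable constants:

| parameter | default | meaning |
|---|---|---|
| `min_measurable_diameter_mm` | 10 | measurability threshold, inclusive |
| `max_targets` | 5 | target-lesion cap per timepoint |
| `pr_threshold_pct` | −30 | SLD change at/below which the case is PR |
| `pd_threshold_pct` | +20 | SLD change at/above which the case is PD |
| `pd_min_absolute_increase_mm` | 5 | absolute increase additionally required for PD (0 disables) |
| `cr_requires_zero_targets` | TRUE | CR when no measurable target remains |

Design choices where practice genuinely varies:

* **Measurability boundary.** "More than 10 mm" and "at least 10 mm" both
  circulate; RECIST 1.1 itself uses ≥ 10 mm, and that inclusive reading is
  the default (a 10.0 mm lesion is measurable). The threshold is a config
  field, not a constant.
* **Baseline-referenced progression.** Percent change is computed against
  the baseline SLD, not against the nadir over multiple follow-ups. The
  package assesses exactly one baseline/follow-up pair; nadir tracking is
  out of scope.
* **Count-based new-lesion rule.** New lesions are flagged when the
  follow-up yields *more* target lesions than baseline. This is the rule a
  tracking-free automated pipeline can actually apply; canonical RECIST
  identifies new lesions by appearance, which requires lesion identity
  across timepoints that neither this package nor the pipelines it models
  attempt. A consequence worth knowing: a new lesion appearing while
  another disappears is invisible to the count.
* **Target re-selection.** Targets are re-derived independently at
  follow-up from the follow-up segmentation; there is no matching of
  baseline targets to follow-up lesions.
* **The +5 mm clause.** Whether simple rule-based implementations apply
  RECIST's absolute-increase requirement for PD varies; it is on by default
  and can be disabled (`pd_min_absolute_increase_mm = 0`).
* **CR on sub-threshold residue.** If all follow-up lesions fall below
  10 mm but are non-zero, the target sum is 0 and the default
  classification is CR. Setting `cr_requires_zero_targets = FALSE` demands
  a truly empty follow-up mask instead.
* **Ties.** Target selection orders by diameter (descending), then volume
  (descending), then lesion id (ascending) — fully deterministic.

The rule order in `classify_response()` is: new lesions → PD; follow-up sum
0 → CR; PD thresholds; PR threshold; else SD. Every decision is recorded in
a `rule_trace` so any classification can be audited after the fact.

## Segmentation metrics

Three complementary metrics compare a predicted mask against a reference on
the same grid:

* **DSC** (overlap): `2|A∩B| / (|A|+|B|)`;
* **VS** (volume agreement): `1 − ||A|−|B|| / (|A|+|B|)`, overlap-blind,
  hence provably ≥ DSC on every pair;
* **HD** (worst-case spatial distance): the symmetric set Hausdorff
  distance between foreground voxel centers in physical mm.

Empty masks occur in treated patients, so the conventions are explicit: DSC
and VS are 1 when both masks are empty and DSC is 0 when exactly one is;
HD is undefined (an error) for an empty mask. "HD" here is the full
(100th-percentile) set Hausdorff over all foreground voxels — the most
common reading of an unqualified "HD" — with `percentile = 95` available
for the outlier-robust variant some evaluation suites report. Distances use
voxel centers scaled by spacing; no sub-voxel surface is extracted. The
implementation is an exact chunked nearest-point search; the tests hold it
to the brute-force double loop at 1e-9 relative tolerance.

## Agreement statistics

Evaluating a response-assessment pipeline against a reference standard uses
categorical-agreement machinery:

* `response_confusion()` builds the 4×4 matrix in fixed severity order
  CR, PR, SD, PD.
* `accuracy_ci()` treats overall agreement as a binomial proportion. The
  Clopper–Pearson exact interval is the default — small-cohort accuracies
  are customarily quoted with exact, asymmetric intervals — with Wilson as
  an option.
* `cohen_kappa_ci()` computes unweighted Cohen's kappa with the standard
  large-sample (Fleiss–Cohen–Everitt) variance, clipped to [−1, 1]. An
  asymptotic interval was chosen over a bootstrap for determinism; linear
  and quadratic weights are available for ordinal use. Degenerate inputs
  are defined rather than left to fail: two identical constant raters give
  kappa 1 (with a warning), two different constant raters give kappa 0.
* `response_auc()` reduces the 4-category assessment to one discrimination
  number. There is no canonical way to do this, so both common
  constructions are implemented and labelled: the default **ordinal** mode
  scores the rater's category by severity rank and computes the
  Mann–Whitney concordance against the binarized reference responder
  status (CR/PR vs SD/PD, ties at ½); **macro_ovr** computes one-vs-rest
  AUCs per category and macro-averages. Both are reconstructions of how a
  single AUC can summarize a 4-category assessment, not claims about any
  particular published computation.

## The phantom generator

Real cohorts of treated liver metastases are private; the package therefore
ships a generator whose cases have *analytic* ground truth. A phantom is an
ellipsoidal liver containing spherical (or axis-aligned ellipsoidal)
lesions, rasterized by voxel-center inclusion on a 96×96×24 grid at
(1.5, 1.5, 4) mm — the in-plane resolution and slice thickness of a typical
abdominal DWI protocol. Voxel-center rasterization matches the
center-to-center measurement convention, which is what makes the analytic
diameters directly comparable to measured ones.

A longitudinal case rescales each baseline lesion about its center by a
per-lesion factor (0 removes it) and may add lesions; the implied true
category is computed *at specification time* by running the same response
rules on the analytic diameters, and generation refuses two classes of
fragile case:

* geometry violating the spec invariants (lesion not inside the liver,
  surfaces closer than two voxels — which would silently merge components);
* near-threshold cases, when a hard true category is requested and the true
  percent change lies within 5 percentage points of a PR/PD threshold,
  where voxelization error could flip the label.

`random_longitudinal_spec()` draws category-conditioned cases used
throughout the tests: 1–5 spherical lesions of 14–34 mm; disappearance for
CR; uniform shrinkage to 50–62% for PR (with baseline lesions of 24–30 mm so
every scaled lesion stays ≥ 12 mm, clear of the measurability boundary);
90–108% for SD; and for PD either growth to ≥ 135% with a guaranteed
7.5 mm absolute SLD increase, or an unchanged baseline of ≤ 4 lesions plus
one new 14–20 mm lesion exercising the count rule. All draws are seeded and
bit-reproducible.

What passing the recovery suite shows — and what it does not: over 200
seeded cases spanning all four categories, the full pipeline (rasterize →
extract → measure → classify) returns the generator's true category without
error. That validates the measurement and rule chain under controlled
geometry. It does *not* bound performance on clinical data, where the hard
part is segmentation quality, irregular lesion shape, and confluent disease;
phantoms here are convex, well-separated solids with noise-free masks.

`split_cohort()` rounds out the harness: a seeded shuffle plus
largest-remainder apportionment (train absorbs surplus first), so 86 cases
at 6:2:2 split 52/17/17, deterministically.

## The two-stage segmentation network

The package includes a compact pure-R 3D U-Net so the cascaded
liver-then-lesion idea can be exercised end to end on phantoms: stage 1
segments the liver from the full volume; the input is masked to the
predicted liver and passed to stage 2; the stage-2 output is intersected
with the liver mask, so predicted tumour ⊆ predicted liver holds by
construction, not by training.

Preprocessing is trilinear resize to the configured input shape followed by
z-score intensity normalization (a constant volume becomes zeros with a
warning). Augmentation samples a through-plane skew angle and an in-plane
shear angle from 0–5° (random sign) and a per-axis translation of ±10% of
the extent, applying the same transform to image (trilinear) and mask
(nearest-neighbour, so labels stay binary).

Two presets exist. The `full` preset records a full-scale recipe
(224×224×64 inputs, 300 epochs, batch 2, Adam at 0.01, Dice loss) as a
configuration object. The `desk` preset — the one the tests actually train —
is sized for a single CPU: 64×64×16 inputs, a 2-level U-Net (one pooling
stage) with 8 base filters, 5 epochs, Adam at 0.003. Three of those desk
numbers are deliberate deviations from a full-scale setup and worth
explaining:

* **depth and width** (2 levels, 8 filters): a 4-level, 16-filter network
  at this input size trains minutes-to-hours in interpreted R for no gain
  on two-level-contrast phantoms; the small net keeps the smoke-training
  contract (final Dice loss below initial on 8 phantoms) in the tens of
  seconds;
* **learning rate 0.003**: at this tiny scale Adam at 0.01 oscillates and
  can finish above its starting loss; 0.003 converges monotonically on the
  same data;
* **Dice-loss smoothing** 1e-5 and probability threshold 0.5 for both
  stages are unexceptional defaults, exposed in the config.

The convolutions are computed as 27 per-offset matrix products against a
zero-padded gather of the feature matrix, which keeps the arithmetic in
BLAS; the backward pass is validated against finite differences in the test
suite. Training is seeded end to end: identical config and seed give an
identical loss history.

The lesion stage deserves a caveat: with lesions occupying a few percent of
the volume, five desk-scale epochs are usually not enough for the Dice loss
to escape the all-background solution, and the smoke contract is carried by
the liver stage (whose loss drops from ≈0.5 to ≈0.05). This is the expected
behaviour of Dice loss on extreme class imbalance at tiny scale, not a
defect the tests hide — the subset guarantee and the two-stage
plumbing are still exercised.

## Problem sizes and runtime

All empirical statements above are the ones the test suite and
`scripts/acceptance.R` themselves compute, at these sizes: 200 longitudinal
phantoms (96×96×24 voxels) for category recovery; 100 random lesions and
digitized spheres of 10–40 mm for the diameter oracle; 50 random mask pairs
(≤ ~700 foreground voxels) for the metric oracles; 500–1000 label
permutations for the null-AUC calibration; 8 phantoms for smoke training.
The full suite runs in about two minutes on one CPU.

## Known limitations

* One baseline and one follow-up; no nadir reference, no multi-timepoint
  series.
* No non-target lesion evaluation, no nodal short-axis rules, no
  unequivocal-progression clause — the engine covers the measurable-disease
  arithmetic of RECIST 1.1, which is what a mask-driven program can apply.
* Masks must share a grid; DICOM reading, resampling and registration are
  out of scope (NIfTI in, NIfTI out).
* The new-lesion rule is count-based by design (see above).
* Phantoms do not emulate DWI intensities beyond two-level contrast, nor
  irregular or confluent lesions.
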