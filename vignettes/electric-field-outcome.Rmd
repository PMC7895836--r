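---
title: "Relating simulated ECT electric fields to clinical outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating simulated ECT electric fields to clinical outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectfield)
```

## The problem

In electroconvulsive therapy (ECT) the electrode placement — right
unilateral (RUL) or bilateral (BL) — shapes the electric field induced in
the brain, and individual head anatomy modulates it further. Given
per-patient field simulations warped to a common (MNI-like) space,
two questions arise:

1. *Where* does one electrode placement produce a systematically stronger
   field than the other, within the same patients?
2. Does the local field strength *predict* clinical outcome (the
   Montgomery–Åsberg Depression Rating Scale, MADRS, after the course),
   once clinical covariates are accounted for?

`ectfield` implements the statistical pipeline for both questions on
voxel-wise field-magnitude stacks. It deliberately does **not** solve for
fields (no finite-element modelling, no segmentation, no registration):
inputs are NIfTI volumes already sharing one grid.

## The model

### Field preparation

Quasi-static field solutions are linear in the injected current, so a
solve at 1 mA is rescaled by a single factor to the device output —
`scaling_spec()` defaults to 900 for a 0.9 A constant-current device; a
0.8 A device uses 800. Only the per-voxel field *magnitude* (V/m) enters
the statistics; direction is discarded. `conductivity_defaults()` records
the isotropic tissue conductivities conventionally used upstream (white
matter 0.126 S/m, gray matter 0.275, CSF 1.654, bone 0.01, scalp 0.465,
eyes 0.5) purely as provenance metadata.

### The inverse voxel-wise GLM

For the outcome analysis the regression direction is the *reverse* of the
conventional neuroimaging GLM: at each voxel $v$ the clinical outcome is
the dependent variable and the voxel's field the independent variable,

$$ y_i = \beta_0 + \beta_E E_{iv} + \boldsymbol{\gamma}^\top \mathbf{z}_i
   + \varepsilon_i , $$

with covariates $\mathbf{z}$ (age, sex, baseline MADRS, total sessions,
mean seizure threshold and, where groups are mixed, a placement-switch
indicator). Because the regressor of interest differs at every voxel, the
design matrix must be solved per voxel; `fit_voxelwise()` does this with a
QR residualization (Frisch–Waugh), which is numerically equal to the
per-voxel pseudoinverse solve — the test suite holds it to an explicit
normal-equations oracle at $10^{-8}$. Reported per voxel: $\hat\beta_E$,
its $t$ statistic, full-model $R^2$, and the semi-partial $R^2$ of the
field (outcome variance uniquely attributable to the field after the
covariates), $sp R^2 = t^2 (1 - R^2) / \mathrm{df}$.

Missing baseline MADRS scores are mean-imputed once on the cohort
(`impute_baseline()`), never inside the permutation loop. A binary
responder outcome (≥ 50% MADRS reduction; remission = end score ≤ 10) is
handled by the same linear machinery as a linear probability model;
logistic regression would be the textbook alternative, but a single
least-squares engine for both outcomes keeps the permutation scheme
uniform, and the permutation inference does not rely on the Gaussian
likelihood.

### TFCE

Threshold-free cluster enhancement integrates cluster support over all
heights instead of fixing a cluster-forming threshold:

$$ \mathrm{TFCE}(v) = \sum_{h = dh, 2dh, \dots}
   e(v, h)^{E} \, h^{H} \, dh , $$

where $e(v,h)$ is the voxel count of the connected component containing
$v$ in $\{t \ge h\}$. Defaults are the canonical volumetric settings
$H = 2$, $E = 0.5$, $dh = \max/100$, 26-connectivity; all are
configurable (`tfce_params()`). By default $dh$ is recomputed from each
map's maximum — *including separately within every permutation*, matching
the canonical implementation; a fixed `dh` is available when scores must
be comparable across maps. Negative associations are assessed by a second
pass on the negated map.

One numerical subtlety: with $dh = \max/n$ the map maximum lies exactly
on the top threshold, so the comparison $t \ge h$ uses a relative slack
($10^{-9} dh$) to keep the peak's top integration step stable against
last-ulp rounding. Without it, two algebraically identical solvers can
differ by a whole step at the peak.

### Permutation inference

Family-wise error is controlled by the permutation distribution of the
map-wide *maximum* TFCE score, each direction tested one-sided at
$\alpha = 0.05$ (the convention of the reference tools; a
correction across the two directions can be layered on by halving
$\alpha$):

- **Paired field comparison** (`sign_flip_test()`): per-subject BL − RUL
  difference maps; under exchangeable symmetric errors each subject's
  difference may be negated, so each permutation draws independent ±1
  signs, recomputes the one-sample $t$ map and its TFCE, and records the
  maximum. Defaults to 5000 permutations.
- **Inverse GLM** (`glm_permutation_test()`): outcome structure is
  permuted while the per-voxel fields stay fixed. The default scheme is
  Freedman–Lane — regress $y$ on the nuisance covariates once, permute
  those residuals, add back the nuisance fit, refit the full model at
  every voxel — which is the default of the reference randomisation tool;
  unrestricted permutation of $y$ is available. Defaults to 20,000
  permutations.

Corrected p-values are $(1 + \#\{\text{null max} \ge \text{obs}\}) /
(1 + n_\text{perm})$, so the identity permutation guarantees
$p \ge 1/(1+n_\text{perm})$ and p never equals 0. When the full group is
no larger than the requested permutations ($2^n$ sign patterns or $n!$
orderings) the test switches to exhaustive enumeration and is exact; the
suite verifies exact agreement with an independent full-enumeration
oracle. Monte-Carlo draws use one RNG stream per permutation index
(seeded `seed + index`), so results are bitwise independent of chunking
or worker layout.

### Cluster reporting

`extract_clusters()` turns the FWER-significant voxel set into the usual
cluster table: size in mm³ (voxel count × voxel volume from the affine
determinant), peak voxel and world (MNI-like) coordinate, peak corrected
p (ties broken by |t|, then voxel index), and cluster-mean $R^2$ /
semi-partial $R^2$. Effect sizes averaged over voxels *selected for
significance* are optimistically biased by that selection; the table
carries a standing `selection_biased` attribute and the print method says
so. Covariate-adjusted scatter pairs for visualization come from
`residualize_pair()` / `cluster_effect_summary()`. Anatomical labelling
requires an atlas and is out of scope; a free-text label column is
provided.

## The synthetic cohort generator

Real cohorts of this kind (per-patient MRI-derived head models) are not
redistributable, so `synthetic_spec()` + `generate_fields()` +
`generate_cohort()` provide a fully in-silico stand-in that preserves the
statistical structure the pipeline assumes, at desk scale:

- **Grid**: 24 × 28 × 24 voxels at 4 mm (≈ 5,700 brain-mask voxels in an
  ellipsoid), large enough for genuine 3D cluster geometry, small enough
  that thousand-permutation runs take seconds.
- **Fields**: `base profile × subject scale × (1 + perturbation)`,
  clipped at 0. The base profile decays (Lorentzian, 50 mm length, 250
  V/m per focus) from one right-lateral "electrode" focus for RUL and two
  temporal foci for BL, giving whole-brain magnitudes of roughly 50–300
  V/m after device scaling and a striking RUL/BL asymmetry. Switchers get
  both placements from one head (shared scale and perturbation).
- **Between-subject variability**: a lognormal global scale (SD 0.1,
  unit mean) for dose/anatomy differences, times a smooth local
  perturbation — Gaussian-smoothed white noise, FWHM 3 voxels (12 mm),
  multiplicative SD 0.15. The smoothness value is a choice, not an
  estimate: no spatial covariance model for between-subject field
  variability is established, so the generator documents rather than
  claims realism here. Local variability is deliberately the dominant
  term; if the global scale dominated, every voxel would be an almost
  perfect proxy of every other and no spatial question would be
  answerable at all (see *Limitations*).
- **Covariates and outcome**: marginals of a severe, largely
  late-life depression ECT cohort — age N(58, 15), baseline MADRS
  N(35.7, 8.3), sessions round N(17.8, 7.5) ≥ 1, seizure threshold
  N(55.3, 34.3) mC truncated positive, 61% female; default group sizes
  25 RUL / 16 BL / 26 switchers. The outcome is linear in the mean field
  over a planted sphere (center, radius and slope set in the spec) plus
  covariate effects and N(0, 8) residual noise; a positive slope means
  higher field → higher end-MADRS (worse outcome). Responder/remitter
  flags follow their definitions; a configurable number of baseline
  scores (default 2) is blanked to exercise imputation. End scores are
  *not* clipped to the MADRS range: keeping the model exactly linear is
  worth a rare negative score in a generator whose purpose is
  statistical, not clinical, realism.
- Everything is a pure function of the spec's single seed (R's
  Mersenne-Twister), bitwise reproducible.

`slope_for_power()` computes the slope giving a target power for the
ROI-level test (normal approximation), used to plant effects of
calibrated detectability.

## What the validation suite shows — and what it cannot

The acceptance tests (in `tests/testthat/test-acceptance.R`) check, at
sizes chosen to keep the default run in minutes: TFCE equality with a
brute-force threshold-loop + flood-fill oracle (20 random 8³ maps,
10⁻¹⁰); exactness of both permutation tests against full enumeration
(n = 4–10 sign patterns, 6! outcome orderings); family-wise false-positive
calibration on 200 null cohorts (n = 40, 1000 Freedman–Lane permutations
— scaled down from the 20,000 a real analysis would use; the binomial
95% band for 200 draws at 0.05 is [0.02, 0.08]); GLM oracle equality
(6³ stack, n = 30, the full covariate design); bitwise determinism; and
the worked 0.5 V/m × 900 = 450 V/m scaling example.

A planted-sphere recovery study (50 seeds, n = 60, radius-3 sphere,
slope at ≈90% ROI-level power) asks for Dice ≥ 0.5 between the
significant set and the truth in ≥ 80% of seeds. Under this generator
that target is not met, and the reason is instructive rather than a
defect of the inference: because the outcome is driven by the subject's
ROI dose and all of a subject's voxels share the global scale factor,
*distant* voxels correlate ≈ 0.5 with the planted regressor. The
marginal voxel-wise model therefore sees genuine (indirect) signal
everywhere — mean t ≈ 1.7 far-field vs ≈ 2.8 in-sphere — and TFCE either
spreads significance over a large diffuse region or, at this effect
size, finds nothing. This is exactly the localization caveat that
applies to real spatially-coherent dose effects: mass-univariate maps
localize *association*, not *mechanism*, when a global dose component is
present. The FWER calibration is unaffected (under the null there is no
dose effect to be a proxy of).

Passing these tests shows the machinery is correct and calibrated under
the generator's assumptions — Gaussian, exchangeable, spatially smooth
errors. It does not certify behavior on real data with non-Gaussian
outcomes, registration error, or anatomy-dependent field uncertainty.

## Numerical choices and degenerate inputs

- Voxels whose field does not vary across subjects (after covariate
  residualization, relative tolerance 10⁻¹²) get $t = 0$ and
  $spR^2 = 0$ and are flagged, keeping map geometry intact rather than
  shrinking the mask.
- A constant outcome (zero variance given the nuisance model) yields an
  all-zero t map and p = 1 everywhere, by an explicit guard rather than
  0/0 luck.
- NaN inside the analysis mask is an error, never silently a 0: silent
  zeros would bias the GLM.
- All volumes in one analysis must share shape bitwise and affine to
  10⁻⁶ mm; there is no resampling on purpose — a mismatch means the
  upstream registration step was skipped.
- Peak ties (common, since max-statistic p-values are granular) break by
  |t|, then lexicographic voxel index, so reports are reproducible.
- SD maps use the n−1 denominator; p-values use the +1 (add-one)
  permutation formula.

## Worked example

```{r example, eval = FALSE}
library(ectfield)

spec <- synthetic_spec(seed = 42)           # 25 RUL / 16 BL / 26 switchers
fields <- generate_fields(spec)

# paired field comparison in the switchers, BL minus RUL
d <- paired_difference(fields$switch_bl, fields$switch_rul)
flip <- sign_flip_test(d, tfce_params(),
                       permutation_plan("sign_flip", 5000, seed = 42))

# inverse GLM on the BL-treated patients
cohort <- impute_baseline(generate_cohort(spec, fields$bl))
design <- design_spec("end_madrs",
                      c("age", "sex", "baseline_madrs", "total_sessions",
                        "mean_seizure_threshold"))
res <- glm_permutation_test(fields$bl, cohort, design, tfce_params(),
                            permutation_plan("freedman_lane", 20000,
                                             seed = 42))
extract_clusters(res)
```

## Limitations

- No anatomical realism: ellipsoid mask, parametric field profiles, no
  tissue classes, no atlas labels.
- The linear probability model for binary response ignores the
  variance structure of binary outcomes (inference is permutation-based,
  which mitigates but does not remove this).
- Mass-univariate maps cannot separate direct local effects from global
  dose proxies (see the recovery discussion above); interpreting cluster
  boundaries as mechanism boundaries over-reads the method.
- Field *direction* relative to tissue orientation is discarded by
  design; vector-aware statistics are a separate problem.
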