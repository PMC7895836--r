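# ectfield

Voxel-wise analysis relating simulated electroconvulsive-therapy (ECT)
electric-field strength to clinical outcome.

## Who this is for

Groups that simulate per-patient ECT electric fields (finite-element head
models, exported as NIfTI magnitude or vector volumes in a common MNI-like
space) and want to test, with proper family-wise error control, (a) where
bilateral (BL) and right-unilateral (RUL) electrode placements differ
within the same patients, and (b) whether local field strength predicts
treatment outcome after covariate adjustment. The package provides the
statistics only — no field solving, segmentation or registration.

## The model

At every brain voxel *v* an **inverse GLM** is fitted — the imaging value
is the *independent* variable, the clinic the *dependent* one:

    end-MADRS_i = b0 + bE * E_iv + gamma' z_i + eps_i

with covariates z (age, sex, baseline MADRS, total sessions, mean seizure
threshold, and a placement-switch flag where groups are mixed). Because
the regressor of interest changes at every voxel, the least-squares
problem is solved per voxel (QR residualization, numerically equal to a
per-voxel pseudoinverse). The t-map of bE is enhanced with **TFCE**
(threshold-free cluster enhancement; H = 2, E = 0.5, dh = max/100,
26-connectivity by default):

    TFCE(v) = sum_h e(v,h)^E * h^H * dh

and corrected p-values come from **max-statistic permutation testing**:
Freedman–Lane outcome permutation for the GLM (default 20,000
permutations) and subject-level **sign flipping** for the paired BL − RUL
field comparison (default 5,000), each direction one-sided at alpha =
0.05, with p = (1 + #{null max >= obs}) / (1 + n_perm). Exhaustive
enumeration switches on automatically for tiny samples, making the tests
exact. Significant voxels are reported as clusters: size in mm³, peak
MNI-like coordinate, peak corrected p, cluster-mean R² and semi-partial
R² (flagged as selection-biased), plus covariate-adjusted scatter data.

A fully seeded **synthetic-cohort generator** (smooth random fields with
RUL/BL electrode profiles, realistic covariate marginals, a planted
spherical effect) stands in for non-shareable patient data; it drives the
entire test suite. See the methods vignette
(`vignettes/electric-field-outcome.Rmd`) for assumptions and limitations.

## Worked example

```r
library(ectfield)

spec   <- synthetic_spec(seed = 42)        # 25 RUL / 16 BL / 26 switchers
fields <- generate_fields(spec)

# 1. paired field comparison in switchers: BL minus RUL, sign-flipping
d    <- paired_difference(fields$switch_bl, fields$switch_rul)
flip <- sign_flip_test(d, tfce_params(),
                       permutation_plan("sign_flip", 1000, seed = 42))
flip
#> <ef_perm_result> scheme 'sign_flip', 1000 Monte-Carlo permutations, alpha 0.05
#>   significant voxels: 5688 positive, 0 negative

# 2. inverse GLM in the BL-treated group
cohort <- impute_baseline(generate_cohort(spec, fields$bl))
design <- design_spec("end_madrs",
                      c("age", "sex", "baseline_madrs", "total_sessions",
                        "mean_seizure_threshold"))
res <- glm_permutation_test(fields$bl, cohort, design, tfce_params(),
                            permutation_plan("freedman_lane", 2000,
                                             seed = 42))
res
#> <ef_perm_result> scheme 'freedman_lane', 2000 Monte-Carlo permutations, alpha 0.05
#>   significant voxels: 0 positive, 0 negative
min(res$p_corrected$positive$values)
#> [1] 0.3978011
```

The sign-flip test finds the BL field significantly stronger than the RUL
field over essentially the whole (synthetic) brain — the second electrode
adds a focus the RUL montage lacks — and no voxel where RUL exceeds BL.
The null-effect cohort (the default plants no outcome effect,
`effect$beta = 0`) correctly yields no significant field–outcome cluster;
the smallest corrected p is far above 0.05. Planting an effect
(`effect = list(center = c(5, 13, 9), radius = 3, beta = 0.25)`) makes
`extract_clusters(res)` return the cluster table with sizes, peaks and
effect sizes.

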