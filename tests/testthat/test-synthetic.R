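test_that("generation is a pure function of the seed", {
  sp <- synthetic_spec(n_rul = 2, n_bl = 2, n_switch = 2, seed = 77,
                       shape = c(12, 14, 12), voxel_size_mm = 6,
                       effect = list(center = c(4, 7, 6), radius = 2,
                                     beta = 0))
  f1 <- generate_fields(sp)
  f2 <- generate_fields(sp)
  expect_identical(f1$bl$data, f2$bl$data)
  expect_identical(f1$switch_rul$data, f2$switch_rul$data)
  c1 <- generate_cohort(sp, f1$bl)
  c2 <- generate_cohort(sp, f2$bl)
  expect_identical(c1, c2)
  # a different seed changes the data
  f3 <- generate_fields(synthetic_spec(n_rul = 2, n_bl = 2, n_switch = 2,
                                       seed = 78, shape = c(12, 14, 12),
                                       voxel_size_mm = 6))
  expect_false(identical(f1$bl$data, f3$bl$data))
})

test_that("the noise-free limit reproduces the base profile exactly", {
  sp <- synthetic_spec(n_rul = 0, n_bl = 3, n_switch = 0,
                       subject_scale_sd = 0, perturbation_sd = 0,
                       shape = c(12, 14, 12), voxel_size_mm = 6, seed = 5)
  f <- generate_fields(sp)
  base <- ectfield:::synthetic_base_profile(sp, "bl")
  expected <- base[f$bl$linear_index]
  for (s in 1:3) expect_equal(f$bl$data[s, ], expected, tolerance = 1e-12)
})

test_that("the subject mean converges on the base profile", {
  sp <- synthetic_spec(n_rul = 0, n_bl = 200, n_switch = 0, seed = 6,
                       shape = c(12, 14, 12), voxel_size_mm = 6)
  f <- generate_fields(sp)
  base <- ectfield:::synthetic_base_profile(sp, "bl")[f$bl$linear_index]
  mu <- colMeans(f$bl$data)
  se <- apply(f$bl$data, 2, sd) / sqrt(200)
  # per-voxel |mean - base| <= 3 SE, allowing the expected chance excesses
  frac_out <- mean(abs(mu - base) > 3 * se)
  expect_lt(frac_out, 0.02)
})

test_that("switcher stacks are paired and BL exceeds RUL on the left", {
  sp <- synthetic_spec(n_rul = 0, n_bl = 0, n_switch = 4, seed = 8,
                       shape = c(12, 14, 12), voxel_size_mm = 6)
  f <- generate_fields(sp)
  expect_identical(f$switch_rul$subject_ids, f$switch_bl$subject_ids)
  d <- paired_difference(f$switch_bl, f$switch_rul)
  left <- d$grid$affine[1, 1] * d$voxel_index[, 1] + d$grid$affine[1, 4] < -20
  expect_gt(mean(d$data[, left]), 0)      # the extra left focus dominates
})

test_that("outcomes follow the planted linear model", {
  # beta = 0: ROI field carries no information about outcome
  sp0 <- synthetic_spec(n_rul = 0, n_bl = 60, n_switch = 0, seed = 9,
                        n_missing_baseline = 0)
  f0 <- generate_fields(sp0)
  co0 <- generate_cohort(sp0, f0$bl)
  roi0 <- attr(co0, "roi_mean_field")
  sl0 <- summary(lm(end_madrs ~ roi0 + age + sex + baseline_madrs,
                    data = co0))$coefficients["roi0", ]
  expect_lt(abs(sl0["Estimate"]), 3 * sl0["Std. Error"])

  # noiseless limit: exactly affine in the ROI mean given covariates
  spx <- synthetic_spec(n_rul = 0, n_bl = 20, n_switch = 0, seed = 10,
                        effect = list(center = c(5, 13, 9), radius = 3,
                                      beta = 0.1),
                        noise_sd = 1e-12, n_missing_baseline = 0)
  fx <- generate_fields(spx)
  cox <- generate_cohort(spx, fx$bl)
  roix <- attr(cox, "roi_mean_field")
  lin <- cox$end_madrs - (spx$gamma[["age"]] * cox$age +
    spx$gamma[["sex"]] * cox$sex +
    spx$gamma[["baseline_madrs"]] * cox$baseline_madrs +
    spx$gamma[["total_sessions"]] * cox$total_sessions +
    spx$gamma[["mean_seizure_threshold"]] * cox$mean_seizure_threshold +
    spx$gamma[["switched"]] * cox$switched)
  expect_equal(lin, spx$intercept + 0.1 * roix, tolerance = 1e-6)

  # planted slope recovered within 2 SE by OLS on the ROI mean at n = 60
  spb <- synthetic_spec(n_rul = 0, n_bl = 60, n_switch = 0, seed = 11,
                        effect = list(center = c(5, 13, 9), radius = 3,
                                      beta = 0.25),
                        n_missing_baseline = 0)
  fb <- generate_fields(spb)
  cob <- generate_cohort(spb, fb$bl)
  roib <- attr(cob, "roi_mean_field")
  slb <- summary(lm(end_madrs ~ roib + age + sex + baseline_madrs +
                      total_sessions + mean_seizure_threshold,
                    data = cob))$coefficients["roib", ]
  expect_lt(abs(slb["Estimate"] - 0.25), 2 * slb["Std. Error"])
})

test_that("responder and remitter flags satisfy their definitions", {
  sp <- synthetic_spec(n_rul = 0, n_bl = 30, n_switch = 0, seed = 12,
                       n_missing_baseline = 0)
  f <- generate_fields(sp)
  co <- generate_cohort(sp, f$bl)
  expect_identical(co$responder,
                   as.integer((co$baseline_madrs - co$end_madrs) /
                                co$baseline_madrs >= 0.5))
  expect_identical(co$remitter, as.integer(co$end_madrs <= 10))
})

test_that("baseline mean imputation follows the stated rule", {
  tab <- data.frame(subject_id = c("a", "b", "c"),
                    baseline_madrs = c(30, 40, NA))
  out <- impute_baseline(tab)
  expect_equal(out$baseline_madrs[3], 35)
  expect_equal(attr(out, "imputed_rows"), 3L)

  full <- data.frame(subject_id = "a", baseline_madrs = 33)
  expect_equal(impute_baseline(full)$baseline_madrs, 33)
  expect_error(impute_baseline(data.frame(baseline_madrs = c(NA_real_,
                                                             NA_real_))),
               "all baseline")

  # 2 of 67 missing from the cohort generator: imputed value = observed mean
  sp <- synthetic_spec(seed = 13)                 # default 67 subjects
  f <- generate_fields(sp)
  st <- f$bl
  co <- generate_cohort(sp, st)
  expect_equal(sum(is.na(co$baseline_madrs)), 2L)
  imp <- impute_baseline(co)
  miss <- attr(imp, "imputed_rows")
  expect_equal(unique(imp$baseline_madrs[miss]),
               mean(co$baseline_madrs, na.rm = TRUE))
})

test_that("planted effects raise |t| more inside the sphere than far away", {
  ds <- design_spec("end_madrs", c("age", "sex", "baseline_madrs"))
  gap <- vapply(1:4, function(i) {
    sp <- synthetic_spec(n_rul = 0, n_bl = 40, n_switch = 0,
                         seed = 900 + i,
                         effect = list(center = c(5, 13, 9), radius = 3,
                                       beta = 0.3),
                         n_missing_baseline = 0)
    f <- generate_fields(sp)
    fit <- fit_voxelwise(f$bl, generate_cohort(sp, f$bl), ds)
    truth <- f$effect_mask[f$bl$linear_index]
    d <- sqrt(colSums((t(f$bl$voxel_index) - c(5, 13, 9))^2))
    mean(abs(fit$t_map$values[truth])) -
      mean(abs(fit$t_map$values[d > 10]))
  }, numeric(1))
  expect_true(all(gap > 0))
})

test_that("an effect sphere outside the mask is rejected", {
  sp <- synthetic_spec(n_rul = 0, n_bl = 3, n_switch = 0, seed = 14,
                       shape = c(12, 14, 12), voxel_size_mm = 6,
                       effect = list(center = c(0, 0, 0), radius = 2,
                                     beta = 0))
  f <- generate_fields(sp)
  expect_error(generate_cohort(sp, f$bl), "sphere")
})
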