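tp_small <- tfce_params(n_steps = 20)

test_that("an all-zero difference stack gives p = 1 everywhere", {
  d <- diff_stack_from(lapply(1:4, function(i) array(0, c(3, 3, 2))))
  res <- suppressWarnings(    # 2^4 patterns cannot reach alpha; irrelevant here
    sign_flip_test(d, tp_small, permutation_plan("sign_flip", 100, seed = 1)))
  expect_true(all(res$p_corrected$positive$values == 1))
  expect_true(all(res$p_corrected$negative$values == 1))
})

test_that("exhaustive sign flipping reproduces full enumeration exactly", {
  # n = 4 subjects, small fixed integer differences on a 2-voxel support
  arrs <- lapply(list(c(3, 1), c(2, -1), c(4, 2), c(1, 1)), function(v) {
    a <- array(0, c(3, 1, 1)); a[1, 1, 1] <- v[1]; a[2, 1, 1] <- v[2]; a
  })
  d <- diff_stack_from(arrs)
  plan <- permutation_plan("sign_flip", 5000, seed = 3)   # 2^4 << 5000
  res <- suppressWarnings(sign_flip_test(d, tp_small, plan))
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 2L^4L - 1L)
  o <- oracle_signflip_exact(d$data, d$grid$shape, d$linear_index, tp_small)
  expect_equal(res$p_corrected$positive$values, o$p_pos, tolerance = 1e-15)
  expect_equal(res$p_corrected$negative$values, o$p_neg, tolerance = 1e-15)
})

test_that("Monte-Carlo sign flipping agrees with the exact test at n = 10", {
  set.seed(9)
  arrs <- lapply(1:10, function(i) array(rnorm(8, 0.4, 1), c(2, 2, 2)))
  d <- diff_stack_from(arrs)
  exact <- sign_flip_test(d, tp_small,
                          permutation_plan("sign_flip", 2000, seed = 5))
  expect_true(exact$exhaustive)
  mc <- sign_flip_test(d, tp_small,
                       permutation_plan("sign_flip", 1500, seed = 5,
                                        exhaustive = FALSE))
  expect_false(mc$exhaustive)
  pe <- exact$p_corrected$positive$values
  pm <- mc$p_corrected$positive$values
  se <- sqrt(pe * (1 - pe) / 1500)
  expect_true(all(abs(pm - pe) <= 3 * se + 2 / 1500))
})

test_that("permutation results are deterministic and chunk-invariant", {
  st <- rand_stack(9, c(4, 4, 2), seed = 17)
  co <- tiny_cohort(st, seed = 18)
  ds <- design_spec("end_madrs", c("age", "sex"))
  plan <- permutation_plan("freedman_lane", 150, seed = 7)
  r1 <- glm_permutation_test(st, co, ds, tp_small, plan, chunk_size = 37L)
  r2 <- glm_permutation_test(st, co, ds, tp_small, plan, chunk_size = 150L)
  expect_identical(r1$p_corrected$positive$values,
                   r2$p_corrected$positive$values)
  expect_identical(r1$max_null$negative, r2$max_null$negative)
  d <- paired_difference(rand_stack(6, c(3, 3, 3), seed = 19),
                         rand_stack(6, c(3, 3, 3), seed = 20))
  plan_sf <- permutation_plan("sign_flip", 120, seed = 11,
                              exhaustive = FALSE)
  s1 <- sign_flip_test(d, tp_small, plan_sf, chunk_size = 13L)
  s2 <- sign_flip_test(d, tp_small, plan_sf, chunk_size = 120L)
  expect_identical(s1$max_null$positive, s2$max_null$positive)
  expect_identical(s1$p_corrected$positive$values,
                   s2$p_corrected$positive$values)
})

test_that("exhaustive outcome permutation matches full enumeration", {
  set.seed(23)
  arrs <- lapply(1:6, function(i) array(runif(4, 10, 100), c(2, 2, 1)))
  st <- diff_stack_from(arrs)                 # reused as a plain stack
  y <- c(30, 11, 25, 8, 17, 5)
  co <- tiny_cohort(st, outcome = y)
  ds <- design_spec("end_madrs")              # intercept only, n! = 720
  plan <- permutation_plan("unrestricted_y", 1000, seed = 3)
  res <- glm_permutation_test(st, co, ds, tp_small, plan)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 719L)
  o <- oracle_glm_exact(st$data, y, st$grid$shape, st$linear_index,
                        tp_small)
  expect_equal(res$p_corrected$positive$values, o$p_pos, tolerance = 1e-12)
  expect_equal(res$p_corrected$negative$values, o$p_neg, tolerance = 1e-12)
})

test_that("a constant outcome yields a zero t map and p = 1", {
  st <- rand_stack(8, c(3, 3, 2), seed = 29)
  co <- tiny_cohort(st, outcome = rep(12, 8))
  res <- glm_permutation_test(st, co, ds <- design_spec("end_madrs"),
                              tp_small,
                              permutation_plan("unrestricted_y", 50,
                                               seed = 1,
                                               exhaustive = FALSE))
  expect_true(all(res$observed_t$values == 0))
  expect_true(all(res$p_corrected$positive$values == 1))
})

test_that("p values respect the attainable floor and monotone duality", {
  st <- rand_stack(10, c(3, 3, 2), seed = 31)
  co <- tiny_cohort(st, seed = 32)
  # plant a strong association so small p values occur
  co$end_madrs <- 30 - 0.2 * st$data[, 4] + rnorm(10, 0, 0.5)
  B <- 99
  res <- glm_permutation_test(st, co, design_spec("end_madrs"), tp_small,
                              permutation_plan("freedman_lane", B, seed = 2,
                                               exhaustive = FALSE))
  p <- res$p_corrected$negative$values
  expect_true(all(p >= 1 / (1 + B)))
  expect_true(all(p <= 1))
  sig10 <- p < 0.10
  expect_true(all(sig10[p < 0.05]))           # alpha-monotone significance
  # Freedman-Lane and unrestricted runs both execute on the same inputs
  res2 <- glm_permutation_test(st, co, design_spec("end_madrs", "age"),
                               tp_small,
                               permutation_plan("unrestricted_y", 60,
                                                seed = 2,
                                                exhaustive = FALSE))
  expect_s3_class(res2, "ef_perm_result")
})

test_that("too few permutations for alpha triggers a warning", {
  d <- diff_stack_from(lapply(1:3, function(i)
    array(rnorm(4), c(2, 2, 1))))
  expect_warning(sign_flip_test(d, tp_small,
                                permutation_plan("sign_flip", 5, seed = 1,
                                                 alpha = 0.05,
                                                 exhaustive = FALSE)),
                 "few permutations")
})
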