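#' Specification of a synthetic ECT field-and-outcome cohort
#'
#' Defines a desk-scale generative stand-in for a common-space cohort of
#' simulated ECT electric-field magnitudes plus clinical covariates and
#' outcomes. Fields are `base profile x subject scale x (1 + smooth
#' perturbation)`, clipped at zero: the base profile decays from synthetic
#' "electrode" foci (one right-lateral focus for right-unilateral (RUL)
#' placement, two temporal foci for bilateral (BL)), the per-subject scale is
#' lognormal, and the perturbation is Gaussian-smoothed white noise emulating
#' smooth between-subject anatomical variability. Outcomes follow a linear
#' model in the mean field over a planted spherical effect region plus
#' covariates. Covariate marginals default to a typical severe late-life
#' depression ECT cohort: age ~ N(58, 15), baseline MADRS ~ N(35.7, 8.3),
#' total sessions ~ round N(17.8, 7.5) (>= 1), mean seizure threshold ~
#' N(55.3, 34.3) mC truncated positive, 61% female; group sizes default to
#' 25 RUL-only, 16 BL-only and 26 switchers.
#'
#' @param shape grid shape in voxels.
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param n_rul,n_bl,n_switch subjects per electrode-placement group
#'   (switchers get paired RUL and BL fields from one head).
#' @param smoothness_fwhm FWHM (voxels) of the Gaussian kernel giving the
#'   perturbation its spatial covariance.
#' @param subject_scale_sd lognormal SD of the per-subject global field
#'   scale (unit median).
#' @param perturbation_sd SD of the multiplicative local perturbation.
#' @param base_amplitude peak of the base field profile per focus, V/m.
#' @param base_decay_mm Lorentzian decay length of the base profile, mm.
#' @param effect list: `center` 0-based voxel triple, `radius` voxels,
#'   `beta` outcome slope in MADRS points per V/m (0 = global null).
#' @param intercept outcome intercept, MADRS points.
#' @param gamma named covariate coefficients on the outcome (age, sex,
#'   baseline_madrs, total_sessions, mean_seizure_threshold, switched).
#' @param noise_sd outcome residual SD, MADRS points.
#' @param covariates list of marginal parameters (means/SDs, female
#'   fraction).
#' @param n_missing_baseline how many baseline scores to blank (exercises
#'   mean imputation).
#' @param seed integer; generation is a pure function of the spec including
#'   this seed (R's default Mersenne-Twister stream).
#' @return list of class `ef_synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(24, 28, 24), voxel_size_mm = 4,
                           n_rul = 25, n_bl = 16, n_switch = 26,
                           smoothness_fwhm = 3, subject_scale_sd = 0.1,
                           perturbation_sd = 0.15, base_amplitude = 250,
                           base_decay_mm = 50,
                           effect = list(center = c(5, 13, 9), radius = 3,
                                         beta = 0),
                           intercept = -1.3,
                           gamma = c(age = 0.05, sex = -1,
                                     baseline_madrs = 0.3,
                                     total_sessions = 0,
                                     mean_seizure_threshold = 0.02,
                                     switched = 5),
                           noise_sd = 8,
                           covariates = list(age = c(58, 15),
                                             baseline_madrs = c(35.7, 8.3),
                                             total_sessions = c(17.8, 7.5),
                                             seizure_threshold = c(55.3, 34.3),
                                             p_female = 0.61),
                           n_missing_baseline = 2, seed = 1) {
  stopifnot(effect$radius >= 1, noise_sd > 0, smoothness_fwhm >= 0,
            subject_scale_sd >= 0, perturbation_sd >= 0)
  shape <- as.integer(shape)
  if (any(shape < 4L)) stop("degenerate grid")
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -voxel_size_mm * (shape - 1) / 2
  spec <- list(shape = shape, voxel_size_mm = voxel_size_mm,
               grid = ef_grid(shape, affine),
               n_rul = n_rul, n_bl = n_bl, n_switch = n_switch,
               smoothness_fwhm = smoothness_fwhm,
               subject_scale_sd = subject_scale_sd,
               perturbation_sd = perturbation_sd,
               base_amplitude = base_amplitude,
               base_decay_mm = base_decay_mm,
               effect = effect, intercept = intercept, gamma = gamma,
               noise_sd = noise_sd, covariates = covariates,
               n_missing_baseline = n_missing_baseline, seed = seed)
  class(spec) <- "ef_synthetic_spec"
  spec
}

# Ellipsoidal brain-like mask with a margin inside the grid.
synthetic_mask <- function(spec) {
  g <- spec$grid
  semi <- (g$shape / 2 - 1.5) * spec$voxel_size_mm
  idx <- as.matrix(expand.grid(i = 0:(g$shape[1] - 1),
                               j = 0:(g$shape[2] - 1),
                               k = 0:(g$shape[3] - 1)))
  xyz <- voxel_to_world(g, idx)
  inside <- (xyz[, 1] / semi[1])^2 + (xyz[, 2] / semi[2])^2 +
    (xyz[, 3] / semi[3])^2 <= 1
  array(inside, dim = g$shape)
}

# Lorentzian decay of the mean field from one focus per electrode; BL has two
# temporal foci, RUL a single right-lateral one.
synthetic_base_profile <- function(spec, placement = c("rul", "bl")) {
  placement <- match.arg(placement)
  g <- spec$grid
  foci <- if (placement == "rul") rbind(c(38, 6, -6))
          else rbind(c(38, 6, -6), c(-38, 6, -6))
  idx <- as.matrix(expand.grid(i = 0:(g$shape[1] - 1),
                               j = 0:(g$shape[2] - 1),
                               k = 0:(g$shape[3] - 1)))
  xyz <- voxel_to_world(g, idx)
  lam2 <- spec$base_decay_mm^2
  base <- 0
  for (f in seq_len(nrow(foci))) {
    d2 <- (xyz[, 1] - foci[f, 1])^2 + (xyz[, 2] - foci[f, 2])^2 +
      (xyz[, 3] - foci[f, 3])^2
    base <- base + spec$base_amplitude * lam2 / (lam2 + d2)
  }
  array(base, dim = g$shape)
}

# Separable Gaussian smoothing with zero padding at the edges.
gaussian_smooth_3d <- function(arr, fwhm_vox) {
  if (fwhm_vox <= 0) return(arr)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, 0, sigma)
  w <- w / sum(w)
  conv1 <- function(a) {
    out <- array(0, dim(a))
    nx <- dim(a)[1]
    for (k in -r:r) {
      src <- max(1, 1 - k):min(nx, nx - k)
      out[src + k, , ] <- out[src + k, , ] + w[k + r + 1] * a[src, , ]
    }
    out
  }
  for (ax in 1:3) arr <- aperm(conv1(arr), c(2, 3, 1))
  arr
}

# ||kernel||_2^3: factor by which separable smoothing shrinks white-noise SD.
smooth_l2_factor <- function(fwhm_vox) {
  if (fwhm_vox <= 0) return(1)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, 0, sigma)
  w <- w / sum(w)
  sqrt(sum(w^2))^3
}

#' Generate synthetic per-subject field stacks
#'
#' Draws every group defined by the spec from one seeded RNG stream:
#' RUL-only and BL-only stacks, plus paired RUL/BL stacks for switchers in
#' which the two placements share one subject scale and one anatomical
#' perturbation (same head, different electrodes).
#'
#' @param spec an [synthetic_spec()].
#' @return list with `ef_field_stack`s `rul`, `bl`, `switch_rul`,
#'   `switch_bl` (NULL when the group size is 0), the `grid`, the dense
#'   logical `mask`, and `effect_mask` (dense logical ground-truth sphere).
#' @export
generate_fields <- function(spec) {
  set.seed(spec$seed)
  mask <- synthetic_mask(spec)
  base <- list(rul = synthetic_base_profile(spec, "rul"),
               bl = synthetic_base_profile(spec, "bl"))
  l2 <- smooth_l2_factor(spec$smoothness_fwhm)
  meanlog <- -spec$subject_scale_sd^2 / 2   # unit-mean global scale

  draw_subject <- function() {
    s <- rlnorm(1, meanlog, spec$subject_scale_sd)
    p <- gaussian_smooth_3d(array(rnorm(prod(spec$shape)), spec$shape),
                            spec$smoothness_fwhm) / l2
    list(scale = s, pert = p)
  }
  field_for <- function(sub, placement)
    pmax(base[[placement]] * sub$scale *
           (1 + spec$perturbation_sd * sub$pert), 0)
  mk_stack <- function(vols, ids)
    build_stack(vols, mask_policy = "explicit", mask = mask,
                subject_ids = ids, grid = spec$grid)

  out <- list(rul = NULL, bl = NULL, switch_rul = NULL, switch_bl = NULL)
  if (spec$n_rul >= 2) {
    vols <- lapply(seq_len(spec$n_rul), function(i)
      field_for(draw_subject(), "rul"))
    out$rul <- mk_stack(vols, sprintf("rul%02d", seq_len(spec$n_rul)))
  }
  if (spec$n_bl >= 2) {
    vols <- lapply(seq_len(spec$n_bl), function(i)
      field_for(draw_subject(), "bl"))
    out$bl <- mk_stack(vols, sprintf("bl%02d", seq_len(spec$n_bl)))
  }
  if (spec$n_switch >= 2) {
    subs <- lapply(seq_len(spec$n_switch), function(i) draw_subject())
    ids <- sprintf("sw%02d", seq_len(spec$n_switch))
    out$switch_rul <- mk_stack(lapply(subs, field_for, "rul"), ids)
    out$switch_bl <- mk_stack(lapply(subs, field_for, "bl"), ids)
  }
  out$grid <- spec$grid
  out$mask <- mask
  out$effect_mask <- effect_sphere_mask(spec)
  out
}

#' Ground-truth effect sphere as a dense logical volume
#'
#' @param spec an [synthetic_spec()].
#' @return dense logical array marking voxels within `effect$radius` voxels
#'   (Euclidean, index space) of `effect$center`.
#' @export
effect_sphere_mask <- function(spec) {
  g <- spec$grid
  ctr <- spec$effect$center
  idx <- as.matrix(expand.grid(i = 0:(g$shape[1] - 1),
                               j = 0:(g$shape[2] - 1),
                               k = 0:(g$shape[3] - 1)))
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2
  array(d2 <= spec$effect$radius^2, dim = g$shape)
}

# Columns of a stack lying in the spec's effect sphere; errors if the sphere
# is not fully inside the analysis mask.
effect_sphere_columns <- function(spec, stack) {
  sph <- effect_sphere_mask(spec)
  lin <- which(sph)
  if (!all(stack$mask[lin])) stop("effect sphere outside the analysis mask")
  match(lin, stack$linear_index)
}

#' Generate a synthetic cohort table for a field stack
#'
#' Covariates are drawn from the spec's marginal distributions and the
#' outcome from the linear model
#' `end_madrs = intercept + beta * roi_mean + gamma' covariates + eps`,
#' where `roi_mean` is the subject's mean field over the planted effect
#' sphere and `eps ~ N(0, noise_sd)`. Responder (>= 50% MADRS reduction) and
#' remitter (end score <= 10) flags are derived before any baseline scores
#' are blanked for the imputation exercise.
#'
#' @param spec an [synthetic_spec()].
#' @param stack the `ef_field_stack` whose fields drive the outcome.
#' @param group optional per-subject group labels (`rul_only`, `bl_only`,
#'   `switcher`); inferred from subject-id prefixes (`rul`/`bl`/`sw`) when
#'   NULL.
#' @return data.frame with columns subject_id, group, age, sex,
#'   baseline_madrs, end_madrs, total_sessions, mean_seizure_threshold,
#'   switched, responder, remitter; the true ROI means and slope are
#'   attached as attributes `roi_mean_field` and `true_beta`.
#' @export
generate_cohort <- function(spec, stack, group = NULL) {
  n <- nrow(stack$data)
  if (is.null(group)) {
    group <- rep(NA_character_, n)
    group[grepl("^rul", stack$subject_ids)] <- "rul_only"
    group[grepl("^bl", stack$subject_ids)] <- "bl_only"
    group[grepl("^sw", stack$subject_ids)] <- "switcher"
    if (anyNA(group))
      stop("cannot infer group from subject ids; pass `group`")
  }
  roi <- rowMeans(stack$data[, effect_sphere_columns(spec, stack),
                             drop = FALSE])
  set.seed(spec$seed + 500009L)
  cv <- spec$covariates
  age <- rnorm(n, cv$age[1], cv$age[2])
  sex <- rbinom(n, 1, cv$p_female)
  baseline <- rnorm(n, cv$baseline_madrs[1], cv$baseline_madrs[2])
  sessions <- pmax(1, round(rnorm(n, cv$total_sessions[1],
                                  cv$total_sessions[2])))
  thr <- rnorm(n, cv$seizure_threshold[1], cv$seizure_threshold[2])
  while (any(thr <= 0))    # truncate positive, deterministic under the seed
    thr[thr <= 0] <- rnorm(sum(thr <= 0), cv$seizure_threshold[1],
                           cv$seizure_threshold[2])
  switched <- as.integer(group == "switcher")
  g <- spec$gamma
  end <- spec$intercept + spec$effect$beta * roi +
    g[["age"]] * age + g[["sex"]] * sex +
    g[["baseline_madrs"]] * baseline + g[["total_sessions"]] * sessions +
    g[["mean_seizure_threshold"]] * thr + g[["switched"]] * switched +
    rnorm(n, 0, spec$noise_sd)
  responder <- as.integer((baseline - end) / baseline >= 0.5)
  remitter <- as.integer(end <= 10)
  n_miss <- min(spec$n_missing_baseline, n - 1L)
  if (n_miss > 0) baseline[sample.int(n, n_miss)] <- NA_real_
  tab <- data.frame(subject_id = stack$subject_ids, group = group,
                    age = age, sex = sex, baseline_madrs = baseline,
                    end_madrs = end, total_sessions = sessions,
                    mean_seizure_threshold = thr, switched = switched,
                    responder = responder, remitter = remitter,
                    stringsAsFactors = FALSE)
  attr(tab, "roi_mean_field") <- roi
  attr(tab, "true_beta") <- spec$effect$beta
  tab
}

#' Mean-impute missing baseline MADRS scores
#'
#' Replaces missing baseline scores by the mean of the observed ones; done
#' once on the cohort, before (never inside) permutation inference.
#'
#' @param cohort a cohort data.frame with a `baseline_madrs` column.
#' @return the cohort with missing baselines imputed; imputed row indices in
#'   attribute `imputed_rows`.
#' @export
impute_baseline <- function(cohort) {
  b <- cohort$baseline_madrs
  miss <- which(is.na(b))
  if (length(miss) == length(b)) stop("all baseline scores missing")
  if (length(miss)) cohort$baseline_madrs[miss] <- mean(b[!is.na(b)])
  attr(cohort, "imputed_rows") <- miss
  cohort
}

#' Approximate outcome slope giving a target ROI-level power
#'
#' Normal-approximation slope for the two-sided single-regressor test of the
#' ROI-mean field at level `alpha`: `beta = (z_{1-alpha/2} + z_power) *
#' noise_sd / (sd(roi_mean) * sqrt(n))`. Used to plant effects of calibrated
#' detectability.
#'
#' @param stack field stack supplying the ROI-mean distribution.
#' @param spec an [synthetic_spec()] (for the sphere and `noise_sd`).
#' @param power target power (default 0.9).
#' @param alpha two-sided level (default 0.05).
#' @return slope in MADRS points per V/m.
#' @export
slope_for_power <- function(stack, spec, power = 0.9, alpha = 0.05) {
  roi <- rowMeans(stack$data[, effect_sphere_columns(spec, stack),
                             drop = FALSE])
  n <- length(roi)
  (qnorm(1 - alpha / 2) + qnorm(power)) * spec$noise_sd / (sd(roi) * sqrt(n))
}
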