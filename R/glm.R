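#' Design specification for the inverse voxel-wise GLM
#'
#' The "inverse" model regresses the clinical outcome on the voxel's field
#' strength (the regressor of interest) plus clinical covariates — the
#' reverse of the usual neuroimaging direction, so the design matrix differs
#' at every voxel and a per-voxel least-squares solve is required.
#'
#' @param outcome `"end_madrs"` (continuous post-course score) or
#'   `"responder"` (binary; fitted with the same linear machinery as a
#'   linear probability model).
#' @param covariates character vector drawn from `age`, `sex`,
#'   `baseline_madrs`, `total_sessions`, `mean_seizure_threshold`,
#'   `switched`.
#' @param include_intercept logical, default TRUE.
#' @return object of class `ef_design_spec`.
#' @export
design_spec <- function(outcome = c("end_madrs", "responder"),
                        covariates = character(),
                        include_intercept = TRUE) {
  outcome <- match.arg(outcome)
  allowed <- c("age", "sex", "baseline_madrs", "total_sessions",
               "mean_seizure_threshold", "switched")
  if (!all(covariates %in% allowed))
    stop("unknown covariates: ",
         paste(setdiff(covariates, allowed), collapse = ", "))
  structure(list(outcome = outcome, covariates = covariates,
                 include_intercept = isTRUE(include_intercept)),
            class = "ef_design_spec")
}

# Outcome vector and nuisance matrix Z = [intercept | covariates] from a
# cohort aligned row-for-row with the stack's subjects.
build_design <- function(stack, cohort, design) {
  n <- nrow(stack$data)
  if (nrow(cohort) != n) stop("cohort rows do not match stack subjects")
  if (!identical(as.character(cohort$subject_id), stack$subject_ids))
    stop("cohort subject_id order does not match the stack")
  y <- cohort[[design$outcome]]
  if (anyNA(y)) stop("missing outcome values")
  Z <- NULL
  if (design$include_intercept) Z <- cbind(`(intercept)` = rep(1, n))
  for (cv in design$covariates) {
    col <- cohort[[cv]]
    if (anyNA(col)) stop("missing values in covariate '", cv,
                         "'; run impute_baseline() first")
    if (sd(col) == 0) stop("covariate '", cv, "' has zero variance")
    Z <- cbind(Z, col)
    colnames(Z)[ncol(Z)] <- cv
  }
  if (is.null(Z)) Z <- matrix(0, n, 0)
  p <- ncol(Z) + 1L                       # + the field regressor
  if (n <= p + 1L) stop("too few subjects for the design (need n > p + 1)")
  list(y = as.numeric(y), Z = Z, p = p, df_resid = n - p)
}

# Core per-voxel statistics by Frisch-Waugh: with Ft and yt the residuals of
# the field columns and outcome on Z, the field coefficient, its t and the
# full-model RSS equal those of the per-voxel full solve.
voxel_t_core <- function(Ft, yt, ff, df, degenerate, y_scale) {
  yy <- sum(yt^2)
  if (yy <= y_scale * 1e-20) {            # outcome constant given nuisance
    z <- numeric(length(ff))
    return(list(beta = z, t = z, rss = rep(0, length(ff)), yy = 0))
  }
  num <- as.numeric(crossprod(Ft, yt))          # t(Ft) %*% yt, length V
  beta <- ifelse(degenerate, 0, num / ifelse(degenerate, 1, ff))
  rss <- pmax(yy - beta^2 * ff, 0)
  denom <- pmax(rss, yy * 1e-14, .Machine$double.xmin)
  tval <- ifelse(degenerate | beta == 0, 0, beta * sqrt(ff * df / denom))
  list(beta = beta, t = tval, rss = rss, yy = yy)
}

#' Fit the inverse GLM at every masked voxel
#'
#' For each voxel v, regresses the outcome y on `[intercept, field_v,
#' covariates]` and reports the field coefficient, its t statistic, the full
#' model R^2 and the semi-partial R^2 of the field (variance uniquely
#' explained by the field after the covariates). Results are numerically
#' equal to an explicit per-voxel pseudoinverse solve; voxels whose field
#' does not vary (after covariate residualization) are flagged and assigned
#' t = 0, sp_r2 = 0 so map geometry stays intact.
#'
#' @param stack an `ef_field_stack`.
#' @param cohort cohort data.frame aligned to the stack (impute first).
#' @param design a [design_spec()].
#' @return `ef_voxel_fit`: stat maps `t_map`, `beta_map`, `r2_full_map`,
#'   `sp_r2_map`, plus `df_resid`, logical `degenerate` flags, and the
#'   design metadata.
#' @export
fit_voxelwise <- function(stack, cohort, design) {
  d <- build_design(stack, cohort, design)
  if (ncol(d$Z) > 0) {
    qz <- qr(d$Z)
    Ft <- qr.resid(qz, stack$data)      # n x V residualized fields
    yt <- qr.resid(qz, d$y)
  } else {
    Ft <- stack$data
    yt <- d$y
  }
  ff <- colSums(Ft^2)
  degenerate <- ff <= max(ff, 1) * 1e-12
  core <- voxel_t_core(Ft, yt, ff, d$df_resid, degenerate,
                       y_scale = max(sum(d$y^2), 1))
  tss <- if (design$include_intercept) sum((d$y - mean(d$y))^2)
         else sum(d$y^2)
  if (tss <= 0) {
    r2 <- rep(0, length(ff)); sp <- rep(0, length(ff))
  } else {
    r2 <- pmin(pmax(1 - core$rss / tss, 0), 1)
    sp <- pmin(pmax(core$beta^2 * ff / tss, 0), r2)
    sp[degenerate] <- 0
  }
  structure(list(t_map = stat_map_like(stack, core$t, "t"),
                 beta_map = stat_map_like(stack, core$beta, "beta"),
                 r2_full_map = stat_map_like(stack, r2, "r2_full"),
                 sp_r2_map = stat_map_like(stack, sp, "sp_r2"),
                 df_resid = d$df_resid, degenerate = degenerate,
                 design = design, n = nrow(stack$data)),
            class = "ef_voxel_fit")
}

#' @export
print.ef_voxel_fit <- function(x, ...) {
  cat("<ef_voxel_fit> outcome '", x$design$outcome, "', ", x$n,
      " subjects, df_resid ", x$df_resid, ", ",
      length(x$t_map$values), " voxels (",
      sum(x$degenerate), " degenerate)\n", sep = "")
  invisible(x)
}

#' Covariate-adjusted pairs for scatter display
#'
#' Residualizes both a per-subject scalar predictor (e.g. the mean field of
#' a significant cluster) and the outcome on `[intercept, covariates]`,
#' giving the added-variable pairs used to visualize a cluster's association
#' with outcome after covariate adjustment.
#'
#' @param x per-subject predictor values.
#' @param y per-subject outcome values.
#' @param covariates numeric matrix or data.frame of covariates (may have 0
#'   columns).
#' @param include_intercept logical, default TRUE.
#' @return data.frame with `x_resid`, `y_resid`.
#' @export
residualize_pair <- function(x, y, covariates = NULL,
                             include_intercept = TRUE) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  Z <- if (include_intercept) cbind(rep(1, n)) else matrix(0, n, 0)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.matrix(as.data.frame(covariates))
    if (nrow(covariates) != n) stop("covariate rows differ from n")
    Z <- cbind(Z, covariates)
  }
  if (ncol(Z) == 0) return(data.frame(x_resid = x, y_resid = y))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient covariate matrix")
  data.frame(x_resid = qr.resid(qz, x), y_resid = qr.resid(qz, y))
}
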