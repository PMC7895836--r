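#' Plan for a max-statistic permutation test
#'
#' @param scheme `"sign_flip"` (paired/one-sample difference test),
#'   `"freedman_lane"` (GLM: permute residuals from the nuisance-only model
#'   and add back the nuisance fit) or `"unrestricted_y"` (GLM: permute the
#'   outcome rows directly).
#' @param n_permutations Monte-Carlo draws; defaults to 5000 for sign
#'   flipping and 20000 for the GLM schemes.
#' @param alpha corrected significance level per direction (default 0.05).
#' @param seed RNG seed; permutation b draws from a stream seeded
#'   `seed + b`, so results do not depend on chunking.
#' @param exhaustive force/forbid exhaustive enumeration; `NULL` (default)
#'   switches it on automatically when the full group (2^n sign patterns or
#'   n! orderings) is no larger than `n_permutations`.
#' @return object of class `ef_perm_plan`.
#' @export
permutation_plan <- function(scheme = c("sign_flip", "freedman_lane",
                                        "unrestricted_y"),
                             n_permutations = NULL, alpha = 0.05,
                             seed = 1, exhaustive = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(n_permutations))
    n_permutations <- if (scheme == "sign_flip") 5000L else 20000L
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(scheme = scheme,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = as.integer(seed),
                 exhaustive = exhaustive),
            class = "ef_perm_plan")
}

# ---- permutation draws ------------------------------------------------------

# all 2^n sign patterns, identity (all +1) first
enumerate_signs <- function(n) {
  m <- matrix(1, n, 2^n)
  for (b in seq_len(2^n) - 1L) {
    bits <- bitwAnd(b %/% 2^(seq_len(n) - 1L), 1L)
    m[, b + 1L] <- 1 - 2 * bits
  }
  m
}

# all n! orderings, identity first
enumerate_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- enumerate_perms(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  cidx <- 0L
  for (pos in seq_len(n)) {           # position of element n... keep identity first
    for (j in seq_len(ncol(sub))) {
      cidx <- cidx + 1L
      rest <- sub[, j]
      out[, cidx] <- append(rest, n, after = n - pos)
    }
  }
  # reorder so the identity permutation is column 1
  id <- which(apply(out, 2, function(p) all(p == seq_len(n))))[1]
  out[, c(id, setdiff(seq_len(ncol(out)), id)), drop = FALSE]
}

# Monte-Carlo draws, one RNG stream per permutation index
mc_signs <- function(n, B, seed) {
  vapply(seq_len(B), function(b) {
    set.seed(seed + b)
    sample(c(-1, 1), n, replace = TRUE)
  }, numeric(n))
}
mc_perms <- function(n, B, seed) {
  vapply(seq_len(B), function(b) {
    set.seed(seed + b)
    sample.int(n)
  }, integer(n))
}

# #{null >= v} for each v, via sorted null (ties counted in)
count_ge <- function(null_sorted, vals) {
  length(null_sorted) - findInterval(vals, null_sorted, left.open = TRUE)
}

new_perm_result <- function(stack, observed_t, obs_tfce, max_null, plan,
                            params, n_perm_used, exhaustive) {
  p <- lapply(c(positive = "positive", negative = "negative"), function(d) {
    cnt <- count_ge(sort(max_null[[d]]), obs_tfce[[d]]$values)
    stat_map_like(stack, (1 + cnt) / (1 + n_perm_used),
                  paste0("p_corrected_", d))
  })
  sig <- lapply(p, function(m) {
    s <- array(FALSE, dim = m$grid$shape)
    s[m$linear_index] <- m$values < plan$alpha
    s
  })
  structure(list(observed_t = observed_t, observed_tfce = obs_tfce,
                 max_null = max_null, p_corrected = p,
                 significant = sig, alpha = plan$alpha,
                 scheme = plan$scheme, seed = plan$seed,
                 n_permutations = n_perm_used, exhaustive = exhaustive,
                 tfce = params),
            class = "ef_perm_result")
}

#' @export
print.ef_perm_result <- function(x, ...) {
  cat("<ef_perm_result> scheme '", x$scheme, "', ",
      x$n_permutations, if (x$exhaustive) " exhaustive" else " Monte-Carlo",
      " permutations, alpha ", x$alpha, "\n  significant voxels: ",
      sum(x$significant$positive), " positive, ",
      sum(x$significant$negative), " negative\n", sep = "")
  invisible(x)
}

# one-sample t per voxel for rows weighted by signs (matrix n x B) given the
# (sign-invariant) column sums of squares
one_sample_t_block <- function(D, S, ss) {
  n <- nrow(D)
  M <- crossprod(S, D) / n                       # B x V means
  V <- (rep(ss, each = nrow(M)) - n * M^2) / (n - 1)
  V <- pmax(V, 0)
  se <- sqrt(V / n)
  T <- M / se
  T[!is.finite(T)] <- 0                          # zero-variance voxels
  T
}

dense_from <- function(stack, vals) {
  arr <- array(0, dim = stack$grid$shape)
  arr[stack$linear_index] <- vals
  arr
}

# map-wide max TFCE per permutation (rows of Tb), both directions at once
tfce_max_block <- function(stack, Tb, params) {
  tfce_max_batch_cpp(Tb, stack$linear_index, stack$grid$shape,
                     params$height_power, params$extent_power,
                     params$n_steps, params$connectivity,
                     if (is.null(params$dh)) -1 else params$dh)
}

tfce_masked <- function(stack, tvals, params, direction) {
  arr <- dense_from(stack, tvals)
  if (direction == "negative") arr <- -arr
  sc <- tfce_dense_cpp(as.numeric(arr), dim(arr), params$height_power,
                       params$extent_power, params$n_steps,
                       params$connectivity,
                       if (is.null(params$dh)) -1 else params$dh)
  sc[stack$linear_index]
}

#' Sign-flipping max-TFCE test on a paired difference stack
#'
#' Observed statistic: one-sample t (mean over SE) of the per-subject
#' differences at each voxel. Each permutation multiplies every subject's
#' difference map by an independent +/-1 (valid under symmetric errors),
#' recomputes the t map and its TFCE enhancement in both directions, and
#' records the map-wide maxima; corrected p-values compare the observed TFCE
#' scores against the max-null. With `2^n <= n_permutations` the full sign
#' group is enumerated and the test is exact.
#'
#' @param diff_stack an `ef_field_stack` of paired differences (e.g.
#'   bilateral minus right-unilateral fields).
#' @param params a [tfce_params()].
#' @param plan a [permutation_plan()] with scheme `"sign_flip"`.
#' @param chunk_size permutations per block (memory/speed trade-off only;
#'   results are identical for any value).
#' @return an `ef_perm_result`.
#' @export
sign_flip_test <- function(diff_stack, params = tfce_params(),
                           plan = permutation_plan("sign_flip"),
                           chunk_size = 256L) {
  if (plan$scheme != "sign_flip") stop("plan scheme must be sign_flip")
  D <- diff_stack$data
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 subjects")
  ss <- colSums(D^2)

  exhaustive <- plan$exhaustive
  if (is.null(exhaustive)) exhaustive <- 2^n <= plan$n_permutations
  if (exhaustive) {
    S <- enumerate_signs(n)[, -1L, drop = FALSE]   # identity is perm 0
    B <- ncol(S)
  } else {
    B <- plan$n_permutations
    S <- NULL
  }
  if ((1 / (1 + B)) > plan$alpha)
    warning("so few permutations that no voxel can reach alpha")

  t_obs <- drop(one_sample_t_block(D, matrix(1, n, 1), ss))
  obs_tfce <- list(
    positive = stat_map_like(diff_stack,
                             tfce_masked(diff_stack, t_obs, params,
                                         "positive"), "tfce_positive"),
    negative = stat_map_like(diff_stack,
                             tfce_masked(diff_stack, t_obs, params,
                                         "negative"), "tfce_negative"))

  max_null <- list(positive = numeric(B), negative = numeric(B))
  done <- 0L
  while (done < B) {
    nb <- min(chunk_size, B - done)
    Sb <- if (exhaustive) S[, done + seq_len(nb), drop = FALSE]
          else mc_signs(n, nb, plan$seed + done)   # streams seed+done+1..
    Tb <- one_sample_t_block(D, Sb, ss)
    mx <- tfce_max_block(diff_stack, Tb, params)
    max_null$positive[done + seq_len(nb)] <- mx[, 1]
    max_null$negative[done + seq_len(nb)] <- mx[, 2]
    done <- done + nb
  }
  t_map <- stat_map_like(diff_stack, t_obs, "t")
  new_perm_result(diff_stack, t_map, obs_tfce, max_null, plan, params, B,
                  exhaustive)
}

#' Max-TFCE permutation test for the inverse voxel-wise GLM
#'
#' Observed statistic: the t map of the field regressor from
#' [fit_voxelwise()]. The null is generated by permuting the subjects'
#' outcome structure while the per-voxel field regressors stay fixed —
#' Freedman-Lane by default (regress the outcome on the nuisance covariates
#' once, permute those residuals, add back the nuisance fit, refit the full
#' model at every voxel), or unrestricted permutation of the outcome rows.
#' Family-wise-corrected p-values per direction come from the permutation
#' distribution of the map-wide maximum TFCE score. With `n! <=
#' n_permutations` the full permutation group is enumerated (exact test);
#' otherwise permutations are drawn i.i.d. with replacement and the identity
#' is permutation 0, so the smallest attainable p is
#' `1/(1 + n_permutations)`.
#'
#' @param stack an `ef_field_stack`.
#' @param cohort cohort data.frame aligned to the stack (imputation already
#'   applied — it is done once, never per permutation).
#' @param design a [design_spec()].
#' @param params a [tfce_params()].
#' @param plan a [permutation_plan()] with scheme `"freedman_lane"` or
#'   `"unrestricted_y"`.
#' @param chunk_size permutations per block; result-invariant.
#' @return an `ef_perm_result`.
#' @export
glm_permutation_test <- function(stack, cohort, design,
                                 params = tfce_params(),
                                 plan = permutation_plan("freedman_lane"),
                                 chunk_size = 256L) {
  if (!plan$scheme %in% c("freedman_lane", "unrestricted_y"))
    stop("plan scheme must be freedman_lane or unrestricted_y")
  d <- build_design(stack, cohort, design)
  n <- nrow(stack$data)
  fit <- fit_voxelwise(stack, cohort, design)
  t_obs <- fit$t_map$values

  if (ncol(d$Z) > 0) {
    qz <- qr(d$Z)
    Ft <- qr.resid(qz, stack$data)
    yhat <- qr.fitted(qz, d$y)
    res <- qr.resid(qz, d$y)
  } else {
    qz <- NULL
    Ft <- stack$data
    yhat <- rep(0, n)
    res <- d$y
  }
  ff <- colSums(Ft^2)
  degenerate <- fit$degenerate

  exhaustive <- plan$exhaustive
  if (is.null(exhaustive))
    exhaustive <- factorial(n) <= plan$n_permutations
  if (exhaustive) {
    P <- enumerate_perms(n)[, -1L, drop = FALSE]
    B <- ncol(P)
  } else {
    B <- plan$n_permutations
    P <- NULL
  }
  if ((1 / (1 + B)) > plan$alpha)
    warning("so few permutations that no voxel can reach alpha")

  obs_tfce <- list(
    positive = stat_map_like(stack, tfce_masked(stack, t_obs, params,
                                                "positive"),
                             "tfce_positive"),
    negative = stat_map_like(stack, tfce_masked(stack, t_obs, params,
                                                "negative"),
                             "tfce_negative"))

  max_null <- list(positive = numeric(B), negative = numeric(B))
  done <- 0L
  while (done < B) {
    nb <- min(chunk_size, B - done)
    Pb <- if (exhaustive) P[, done + seq_len(nb), drop = FALSE]
          else mc_perms(n, nb, plan$seed + done)
    # permuted outcomes, one column per permutation
    Ystar <- if (plan$scheme == "freedman_lane")
               yhat + matrix(res[Pb], n, nb)
             else matrix(d$y[Pb], n, nb)
    Yt <- if (!is.null(qz)) qr.resid(qz, Ystar) else Ystar
    NUM <- crossprod(Yt, Ft)                      # nb x V
    ffr <- rep(ff, each = nb)
    BETA <- NUM / ifelse(ffr == 0, 1, ffr)
    yy <- colSums(Yt^2)
    RSS <- pmax(matrix(yy, nb, length(ff)) - BETA^2 * ffr, 0)
    DEN <- pmax(RSS, matrix(yy, nb, length(ff)) * 1e-14,
                .Machine$double.xmin)
    Tb <- BETA * sqrt(ffr * d$df_resid / DEN)
    Tb[, degenerate] <- 0
    Tb[yy <= max(sum(d$y^2), 1) * 1e-20, ] <- 0  # constant permuted outcome
    Tb[!is.finite(Tb)] <- 0
    mx <- tfce_max_block(stack, Tb, params)
    max_null$positive[done + seq_len(nb)] <- mx[, 1]
    max_null$negative[done + seq_len(nb)] <- mx[, 2]
    done <- done + nb
  }
  out <- new_perm_result(stack, fit$t_map, obs_tfce, max_null, plan, params,
                         B, exhaustive)
  out$fit <- fit
  out
}
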