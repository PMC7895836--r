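# Small in-code fixtures shared across tests.

tiny_grid <- function(shape = c(4, 4, 4), vox = 4) {
  aff <- diag(c(rep(vox, 3), 1))
  aff[1:3, 4] <- -vox * (shape - 1) / 2
  ef_grid(shape, aff)
}

# stack of random positive fields on a fully-dense mask
rand_stack <- function(n, shape = c(4, 4, 4), seed = 1, vox = 4) {
  set.seed(seed)
  g <- tiny_grid(shape, vox)
  vols <- lapply(seq_len(n), function(i)
    array(runif(prod(shape), 50, 300), shape))
  build_stack(vols, mask_policy = "explicit",
              mask = array(TRUE, shape), grid = g)
}

# signed difference stack built directly from a list of arrays
diff_stack_from <- function(arrs, vox = 4) {
  shape <- dim(arrs[[1]])
  g <- tiny_grid(shape, vox)
  data <- do.call(rbind, lapply(arrs, as.numeric))
  # column order must match build_stack's (i,j,k)-lexicographic convention
  mask <- array(TRUE, shape)
  idx <- which(mask, arr.ind = TRUE) - 1L
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  lin <- 1L + idx[ord, 1] + shape[1] * (idx[ord, 2] + shape[2] * idx[ord, 3])
  ectfield:::new_field_stack(data[, lin, drop = FALSE], mask, g,
                             paste0("S", seq_along(arrs)),
                             nonnegative = FALSE)
}

# minimal cohort aligned to a stack, covariates drawn at a fixed seed
tiny_cohort <- function(stack, seed = 1, outcome = NULL) {
  set.seed(seed)
  n <- nrow(stack$data)
  data.frame(
    subject_id = stack$subject_ids,
    group = "bl_only",
    age = rnorm(n, 58, 15),
    sex = rbinom(n, 1, 0.6),
    baseline_madrs = rnorm(n, 35.7, 8.3),
    end_madrs = if (is.null(outcome)) rnorm(n, 12.8, 9.5) else outcome,
    total_sessions = pmax(1, round(rnorm(n, 17.8, 7.5))),
    mean_seizure_threshold = abs(rnorm(n, 55.3, 34.3)) + 1,
    switched = rbinom(n, 1, 0.4),
    responder = rbinom(n, 1, 0.66),
    remitter = rbinom(n, 1, 0.51),
    stringsAsFactors = FALSE)
}
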