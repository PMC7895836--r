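# Independent brute-force oracles: deliberately naive implementations used
# only to check the package's optimized paths.

oracle_offsets <- function(conn) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- m > 0 & switch(as.character(conn),
                         "6" = m <= 1, "18" = m <= 2, "26" = m <= 3)
  as.matrix(off[keep, ])
}

# flood-fill component labelling of a logical 3D array
oracle_label <- function(mask, conn = 26) {
  dm <- dim(mask)
  labs <- array(0L, dm)
  offs <- oracle_offsets(conn)
  nxt <- 0L
  for (s in which(mask)) {
    if (labs[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    labs[s] <- nxt
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      v0 <- v - 1L
      vx <- v0 %% dm[1]
      vy <- (v0 %/% dm[1]) %% dm[2]
      vz <- v0 %/% (dm[1] * dm[2])
      for (o in seq_len(nrow(offs))) {
        u <- c(vx, vy, vz) + offs[o, ]
        if (any(u < 0) || any(u >= dm)) next
        ul <- 1L + u[1] + dm[1] * (u[2] + dm[2] * u[3])
        if (mask[ul] && labs[ul] == 0L) {
          labs[ul] <- nxt
          queue <- c(queue, ul)
        }
      }
    }
  }
  labs
}

# threshold-loop TFCE: label the supra-threshold set afresh at every h
oracle_tfce <- function(arr, H = 2, E = 0.5, n_steps = 100, conn = 26,
                        dh = NULL) {
  out <- array(0, dim(arr))
  mx <- max(arr)
  if (mx <= 0) return(out)
  if (is.null(dh)) {
    dh <- mx / n_steps
    K <- n_steps
  } else {
    K <- floor(mx / dh + 1e-9)
  }
  for (k in seq_len(K)) {
    h <- k * dh
    # same slack as the package: the top threshold must include the maximum
    supra <- arr >= h - 1e-9 * dh
    labs <- oracle_label(supra, conn)
    if (max(labs) == 0) next
    sizes <- tabulate(labs[labs > 0])
    sel <- labs > 0
    out[sel] <- out[sel] + sizes[labs[sel]]^E * h^H * dh
  }
  out
}

# textbook OLS via explicit pseudoinverse + residualization, one voxel
oracle_ols <- function(X, y, field_col) {
  n <- nrow(X)
  sv <- svd(X)
  pinv <- sv$v %*% diag(1 / sv$d, length(sv$d)) %*% t(sv$u)
  beta <- drop(pinv %*% y)
  res <- y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(crossprod(X))
  tval <- beta[field_col] / sqrt(covb[field_col, field_col])
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  fit_red <- lm.fit(X[, -field_col, drop = FALSE], y)
  sp_r2 <- (sum(fit_red$residuals^2) - sum(res^2)) / tss
  list(beta = beta[field_col], t = tval, r2 = r2, sp_r2 = sp_r2)
}

# exact sign-flipping max-TFCE test by full enumeration over all 2^n
# patterns (identity included), p(v) = fraction of patterns whose map-wide
# max TFCE >= the observed TFCE at v
oracle_signflip_exact <- function(D, shape, lin, tp) {
  n <- nrow(D)
  tstat <- function(d) apply(d, 2, function(col) {
    s <- sd(col)
    if (s == 0) 0 else mean(col) / (s / sqrt(n))
  })
  tf <- function(tv, dir) {
    arr <- array(0, shape)
    arr[lin] <- tv
    if (dir == "neg") arr <- -arr
    oracle_tfce(arr, tp$height_power, tp$extent_power, tp$n_steps,
                tp$connectivity)[lin]
  }
  obs <- tstat(D)
  obs_pos <- tf(obs, "pos")
  obs_neg <- tf(obs, "neg")
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  mx <- t(apply(signs, 1, function(s) {
    tv <- tstat(D * s)
    c(max(tf(tv, "pos")), max(tf(tv, "neg")))
  }))
  list(p_pos = vapply(obs_pos, function(v) mean(mx[, 1] >= v), numeric(1)),
       p_neg = vapply(obs_neg, function(v) mean(mx[, 2] >= v), numeric(1)))
}

# exact unrestricted-permutation GLM max-TFCE test at one small n,
# per-voxel t from lm(), full n! enumeration
oracle_glm_exact <- function(D, y, shape, lin, tp) {
  n <- nrow(D)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  tstat <- function(yy) apply(D, 2, function(f) {
    if (sd(f) == 0) return(0)
    summary(lm(yy ~ f))$coefficients["f", "t value"]
  })
  tf <- function(tv, dir) {
    arr <- array(0, shape)
    arr[lin] <- tv
    if (dir == "neg") arr <- -arr
    oracle_tfce(arr, tp$height_power, tp$extent_power, tp$n_steps,
                tp$connectivity)[lin]
  }
  obs <- tstat(y)
  obs_pos <- tf(obs, "pos")
  obs_neg <- tf(obs, "neg")
  mx <- t(apply(perms, 1, function(p) {
    tv <- tstat(y[p])
    c(max(tf(tv, "pos")), max(tf(tv, "neg")))
  }))
  list(p_pos = vapply(obs_pos, function(v) mean(mx[, 1] >= v), numeric(1)),
       p_neg = vapply(obs_neg, function(v) mean(mx[, 2] >= v), numeric(1)))
}
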