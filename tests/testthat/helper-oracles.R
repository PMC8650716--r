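# Independent oracles used across tests. These deliberately use naive
# closed forms / brute force, not the package's computation paths.

# HC0 sandwich Wald statistic for the OLS coefficient of column j+1
# (0-based j as in the package API), computed from the textbook formula.
oracle_ols_wald <- function(X, y, j) {
  beta <- solve(crossprod(X), crossprod(X, y))
  r <- as.numeric(y - X %*% beta)
  bread <- solve(crossprod(X))
  meat <- t(X) %*% (X * r^2)
  V <- bread %*% meat %*% bread
  as.numeric(beta[j + 1]^2 / V[j + 1, j + 1])
}

# Exhaustive permutation p-value for the OLS/HC0 Wald test: permute the
# predictor column over all n! arrangements.
oracle_exhaustive_perm_p <- function(X, y, j, perms) {
  W_obs <- oracle_ols_wald(X, y, j)
  W_all <- apply(perms, 1, function(ix) {
    Xp <- X
    Xp[, j + 1] <- X[ix, j + 1]
    oracle_ols_wald(Xp, y, j)
  })
  mean(W_all >= W_obs - 1e-12)
}

# Brute-force voxel-wise gray-matter mask: loops over every voxel.
oracle_gm_mask <- function(stack, lesion_masks, coverage_masks) {
  dims <- dim(stack[[1]]$gm)
  out <- array(FALSE, dims)
  n <- length(stack)
  for (i in seq_len(dims[1])) for (jj in seq_len(dims[2]))
    for (kk in seq_len(dims[3])) {
      gm <- mean(vapply(stack, function(s) s$gm[i, jj, kk], 0))
      wm <- mean(vapply(stack, function(s) s$wm[i, jj, kk], 0))
      csf <- mean(vapply(stack, function(s) s$csf[i, jj, kk], 0))
      if (!(gm >= wm && gm >= csf)) next
      # lesioned in any patient within Euclidean distance <= 1 voxel?
      near_lesion <- FALSE
      for (lm in lesion_masks) {
        for (ii in max(1, i - 1):min(dims[1], i + 1))
          for (j2 in max(1, jj - 1):min(dims[2], jj + 1))
            for (k2 in max(1, kk - 1):min(dims[3], kk + 1)) {
              d2 <- (ii - i)^2 + (j2 - jj)^2 + (k2 - kk)^2
              if (d2 <= 1 && lm[ii, j2, k2]) near_lesion <- TRUE
            }
      }
      if (near_lesion) next
      covered <- all(vapply(coverage_masks,
                            function(cm) cm[i, jj, kk], TRUE))
      if (covered) out[i, jj, kk] <- TRUE
    }
  out
}

random_tissue_stack <- function(n, dims) {
  lapply(seq_len(n), function(i) {
    raw <- array(runif(prod(dims) * 3), c(dims, 3))
    tot <- raw[, , , 1] + raw[, , , 2] + raw[, , , 3]
    list(gm = raw[, , , 1] / tot, wm = raw[, , , 2] / tot,
         csf = raw[, , , 3] / tot)
  })
}

strip_attrs <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# Small repeated-measures dataset: n participants, two occasions.
make_paired_data <- function(n, effect = 0, sd_participant = 1,
                             sd_noise = 1, noise = rnorm) {
  d <- data.frame(participant_id = rep(sprintf("P%02d", 1:n), each = 2),
                  occ = rep(c(0, 1), n))
  d$age <- rep(round(runif(n, 30, 60)), each = 2)
  b <- rnorm(n, 0, sd_participant)
  d$y <- 1 + effect * d$occ + 0.02 * d$age + rep(b, each = 2) +
    sd_noise * noise(2 * n)
  d
}
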