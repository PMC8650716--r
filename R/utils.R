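# Internal helpers shared across modules.

# All permutations of 1..n as a matrix with one permutation per row.
# Only sensible for small n (exhaustive permutation tests).
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      row <- row + 1L
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

# All 2^n sign patterns (+1/-1) as rows.
all_sign_flips <- function(n) {
  stopifnot(n >= 1, n <= 20)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(grid) <- NULL
  grid
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be an integer", name))
  invisible(as.integer(x))
}

# Add-one permutation p-value estimator: valid at any finite n_perm.
perm_pvalue <- function(stat_obs, stat_perm) {
  (1 + sum(stat_perm >= stat_obs - 1e-12)) / (1 + length(stat_perm))
}
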