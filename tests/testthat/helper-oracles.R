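# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths.

# Central finite differences of the layer objective with respect to Y.
fd_gradient <- function(y, x, step = 1e-6) {
  g <- y * 0
  for (i in seq_along(y)) {
    yp <- y; ym <- y
    yp[i] <- yp[i] + step
    ym[i] <- ym[i] - step
    g[i] <- (sf_objective(yp, x) - sf_objective(ym, x)) / (2 * step)
  }
  g
}

# Direct per-column evaluation of the layer objective: soft-absolute
# activation, explicit row then column normalization, explicit L1 norm of
# every normalized column.
naive_objective <- function(y, x, eps = 1e-8) {
  s <- sqrt((t(y) %*% x)^2 + eps)
  for (i in seq_len(nrow(s))) s[i, ] <- s[i, ] / sqrt(sum(s[i, ]^2))
  total <- 0
  for (j in seq_len(ncol(s))) {
    total <- total + sum(abs(s[, j] / sqrt(sum(s[, j]^2))))
  }
  total
}

# Gini coefficient of a nonnegative vector (0 = perfectly even, ->1 sparse).
gini <- function(v) {
  n <- length(v)
  sum(abs(outer(v, v, "-"))) / (2 * n^2 * mean(v))
}

rand_matrix <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc)
}

# Small labelled expression matrix for I/O tests.
toy_expression <- function(n = 3, m = 4, seed = 1) {
  set.seed(seed)
  matrix(round(rnorm(n * m, 10, 2), 3), n, m,
         dimnames = list(paste0("S", seq_len(n)), paste0("G", seq_len(m))))
}
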