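test_that("soft-absolute activation is a smooth, even surrogate of |z|", {
  expect_identical(soft_abs(0), 1e-4)                   # sqrt(eps) floor
  expect_identical(soft_abs(-4), soft_abs(4))
  expect_equal(soft_abs(4), sqrt(16 + 1e-8))
  expect_equal(dim(soft_abs(matrix(0, 2, 3))), c(2L, 3L))
  # derivative at 0 vanishes (central difference)
  h <- 1e-7
  expect_lt(abs(soft_abs(h) - soft_abs(-h)) / (2 * h), 1e-12)
})

test_that("row and column L2 normalization produce unit norms", {
  expect_equal(l2_normalize_rows(matrix(c(3, 4), 1, 2)),
               matrix(c(0.6, 0.8), 1, 2))
  expect_equal(l2_normalize_cols(matrix(c(3, 4), 2, 1)),
               matrix(c(0.6, 0.8), 2, 1))
  i5 <- diag(5)
  expect_equal(l2_normalize_rows(i5), i5)
  # equal positive column entries -> 1/sqrt(t)
  expect_equal(l2_normalize_cols(matrix(2, 4, 1)), matrix(0.5, 4, 1))

  m <- abs(rand_matrix(5, 7, seed = 2)) + 0.1
  expect_lt(max(abs(sqrt(rowSums(l2_normalize_rows(m)^2)) - 1)), 1e-12)
  expect_lt(max(abs(sqrt(colSums(l2_normalize_cols(m)^2)) - 1)), 1e-12)
})

test_that("layer objective matches direct evaluation and its bounds", {
  # t = 1: every normalized column is the scalar 1, so J = m exactly
  y <- rand_matrix(5, 1, seed = 4)
  x <- rand_matrix(5, 7, seed = 5)
  expect_identical(sf_objective(y, x), 7)

  # identical columns: J = m * ||s_hat||_1 for the shared normalized column
  y2 <- rand_matrix(4, 3, seed = 6)
  x2 <- matrix(rnorm(4), 4, 1)[, rep(1, 9)]
  expect_equal(sf_objective(y2, x2), naive_objective(y2, x2),
               tolerance = 1e-10)

  # random instances: agreement with the naive oracle and m <= J <= m sqrt(t)
  for (seed in 1:8) {
    d <- 6; t <- 4; m <- 10
    yr <- rand_matrix(d, t, seed = 100 + seed)
    xr <- rand_matrix(d, m, seed = 200 + seed)
    j <- sf_objective(yr, xr)
    expect_equal(j, naive_objective(yr, xr), tolerance = 1e-10)
    expect_gte(j, m)
    expect_lte(j, m * sqrt(t))
  }

  expect_error(sf_objective(rand_matrix(3, 2, 1), rand_matrix(4, 5, 1)),
               "dimension mismatch")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(42)
  worst <- 0
  for (rep in 1:20) {
    d <- sample(2:8, 1); t <- sample(1:8, 1); m <- sample(2:8, 1)
    y <- matrix(rnorm(d * t), d, t)
    x <- matrix(rnorm(d * m), d, m)
    ga <- sf_gradient(y, x)
    gn <- fd_gradient(y, x)
    # norm-wise relative error; per-component ratios only measure
    # finite-difference noise where the gradient itself vanishes
    rel <- max(abs(ga - gn)) / max(max(abs(gn)), 1e-12)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("gradient is zero for a single filter and gene-order invariant", {
  y <- rand_matrix(6, 1, seed = 9)
  x <- rand_matrix(6, 8, seed = 10)
  expect_identical(sf_gradient(y, x), matrix(0, 6, 1))

  y2 <- rand_matrix(5, 3, seed = 11)
  x2 <- rand_matrix(5, 8, seed = 12)
  p <- sample(8)
  expect_identical(sf_gradient(y2, x2), sf_gradient(y2, x2[, p]))
  expect_identical(sf_objective(y2, x2), sf_objective(y2, x2[, p]))
})

test_that("layer fitting is deterministic, seed-sensitive and descends", {
  x <- rand_matrix(4, 6, seed = 0)
  f1 <- fit_sf_layer(x, 3, seed = 1)
  f2 <- fit_sf_layer(x, 3, seed = 1)
  expect_identical(f1$filter, f2$filter)
  expect_identical(f1$distribution, f2$distribution)

  f3 <- fit_sf_layer(x, 3, seed = 2)
  expect_false(identical(f1$filter, f3$filter))  # random init differs

  for (f in list(f1, f3)) {
    expect_true(all(diff(f$objective_trace) <= 0))
    expect_lte(f$value, f$initial_value)
    expect_identical(f$objective_trace[1], f$initial_value)
    m <- f$n_genes; t <- f$n_filters
    expect_true(all(f$objective_evals >= m - 1e-9))
    expect_true(all(f$objective_evals <= m * sqrt(t) + 1e-9))
    expect_true(all(f$distribution >= 1e-4))
  }
})

test_that("optimization sharpens the population sparsity of gene columns", {
  sim <- simulate_expression(n_samples = 20, n_genes = 120, n_de = 8,
                             effect_size = 3, seed = 21)
  xs <- standardize_samples(sim$expression)
  fit <- fit_sf_layer(xs, 8, seed = 3)

  y0 <- sldsf:::local_seed(3, matrix(rnorm(nrow(xs) * 8), nrow(xs), 8))
  col_gini <- function(y) {
    s_hat <- l2_normalize_cols(l2_normalize_rows(soft_abs(crossprod(y, xs))))
    mean(apply(s_hat, 2, gini))
  }
  expect_gt(col_gini(fit$filter), col_gini(y0))
})
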