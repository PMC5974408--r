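# Smoothing constant of the soft-absolute activation |z| ~ sqrt(z^2 + eps).
.SOFT_ABS_EPS <- 1e-8

# Canonical (gene-order-invariant) numerics.
#
# Floating-point summation depends on accumulation order, so a plain sum over
# gene columns changes in the last ulp when genes are reordered; over a few
# hundred quasi-Newton iterations that rounding difference grows into a
# different optimization path and possibly a different local optimum. Two
# devices make every result of this package exactly invariant to the order
# of the gene columns:
#
#   1. The layer objective and gradient are themselves gene-order-invariant
#      quantities (sums over genes). They are evaluated after permuting the
#      gene columns into a canonical order determined only by the column
#      values (lexicographic sort), so the arithmetic -- plain BLAS -- sees
#      bitwise-identical inputs whatever order the genes arrived in.
#   2. The remaining gene-axis reductions that produce per-sample scalars
#      (row L2 norms, per-sample moments) accumulate their terms in
#      nondecreasing value order, a function of the value multiset only.
#
# Gene-indexed outputs (activations, normalized matrices, scores) are pure
# per-column computations and permute exactly with their input.
canonical_sum <- function(v) sum(sort.int(v, method = "quick"))

# Row sums with each row accumulated in nondecreasing value order (C++).
canonical_rowsums <- function(m) {
  canonical_rowsums_cpp(m)
}

# Permutation placing the columns of x in a canonical (content-determined)
# lexicographic order; any two column-identical matrices map to the same
# sorted matrix. Ties (duplicate columns) are interchangeable.
canonical_col_order <- function(x) {
  do.call(order, c(lapply(seq_len(nrow(x)), function(i) x[i, ]),
                   list(method = "radix")))
}
# L2 norms below this are considered degenerate ...
.NORM_GUARD_THRESHOLD <- 1e-12
# ... and replaced by this constant before division. The soft-absolute floor
# sqrt(eps) = 1e-4 makes true zeros impossible, so the guard only protects
# against underflow; where it fires the norm is treated as a constant in the
# gradient (no projection term).
.NORM_GUARD_VALUE <- 1e-8

#' Soft-absolute activation
#'
#' Smooth surrogate of the absolute value, `sqrt(z^2 + eps)`. It is strictly
#' positive (floor `sqrt(eps) = 1e-4` at z = 0), even, and differentiable
#' everywhere with derivative `z / sqrt(z^2 + eps)` (zero at z = 0), which
#' keeps the sparse-filtering objective smooth.
#'
#' @param z Numeric vector or matrix.
#' @param eps Smoothing constant (default `1e-8`).
#' @return Object of the same shape with elementwise `sqrt(z^2 + eps)`.
#' @export
soft_abs <- function(z, eps = .SOFT_ABS_EPS) {
  stopifnot(is.numeric(z), all(is.finite(z)))
  sqrt(z^2 + eps)
}

guard_norms <- function(nrm) {
  degenerate <- nrm < .NORM_GUARD_THRESHOLD
  nrm[degenerate] <- .NORM_GUARD_VALUE
  list(norm = nrm, degenerate = degenerate)
}

#' L2-normalize the rows of a matrix
#'
#' Divides each row by its L2 norm, the "high dispersal" step of sparse
#' filtering: all rows (learned samples) end up contributing with equal
#' magnitude. Rows with norm below 1e-12 are divided by a small constant
#' instead of their true norm. Row norms are accumulated in sorted order so
#' the result is exactly equivariant under column permutations.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape with unit-L2-norm rows.
#' @export
l2_normalize_rows <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  g <- guard_norms(sqrt(canonical_rowsums(m^2)))
  m / g$norm
}

#' L2-normalize the columns of a matrix
#'
#' Divides each column by its L2 norm, placing every column (gene) on the
#' unit L2 ball so that the L1 objective measures sparsity rather than
#' magnitude. Guarded like [l2_normalize_rows()].
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape with unit-L2-norm columns.
#' @export
l2_normalize_cols <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  g <- guard_norms(sqrt(colSums(m^2)))
  sweep(m, 2L, g$norm, "/")
}

# Forward pass of one sparse-filtering layer. Y: d_in x t filters,
# X: d_in x m input. Returns all intermediates needed by the gradient.
sf_forward <- function(y, x, eps = .SOFT_ABS_EPS) {
  z <- crossprod(y, x)                  # t x m, Y^T X
  s <- sqrt(z^2 + eps)                  # soft-absolute activation
  rg <- guard_norms(sqrt(rowSums(s^2)))
  s_row <- s / rg$norm                  # row-normalized S-tilde
  cg <- guard_norms(sqrt(colSums(s_row^2)))
  s_hat <- sweep(s_row, 2L, cg$norm, "/")  # column-normalized S-hat
  list(z = z, s = s, s_row = s_row, s_hat = s_hat, rg = rg, cg = cg)
}

check_sf_shapes <- function(y, x) {
  if (!is.matrix(y) || !is.matrix(x))
    stop("filter and input must be matrices")
  if (nrow(y) != nrow(x))
    stop("dimension mismatch: filter has ", nrow(y),
         " input rows but input matrix has ", nrow(x))
  if (ncol(x) < 2L) stop("input must have at least 2 columns (genes)")
  if (ncol(y) < 1L) stop("need at least one filter column")
  invisible(TRUE)
}

#' Sparse-filtering layer objective
#'
#' The layer objective is the L1 norm of the normalized sample distribution,
#' `J(Y) = sum_j || S-hat[, j] ||_1` with
#' `S = sqrt((Y^T X)^2 + 1e-8)` soft-absolute activated, `S-tilde` its
#' row-L2-normalized form and `S-hat` the column-L2-normalized form of
#' `S-tilde`. Since all entries of `S-hat` are positive, `J` equals the grand
#' sum of `S-hat`, which avoids an absolute-value kink in the gradient.
#' For an input with `m` genes and `t` filters, `m <= J <= m * sqrt(t)`.
#'
#' The value is computed with the gene columns in canonical order (see the
#' package vignette on reproducibility), so it is bitwise invariant under
#' gene permutations of `x`.
#'
#' @param y Filter matrix, `d_in x t`.
#' @param x Input matrix, `d_in x m`.
#' @return The scalar objective value.
#' @export
sf_objective <- function(y, x) {
  check_sf_shapes(y, x)
  sf_objective_canonical(y, x[, canonical_col_order(x), drop = FALSE])
}

sf_objective_canonical <- function(y, x) {
  sum(sf_forward(y, x)$s_hat)
}

#' Analytic gradient of the sparse-filtering layer objective
#'
#' Back-propagates the all-ones upstream gradient through the column
#' normalization, the row normalization and the soft-absolute activation:
#' for a normalization `u = v / ||v||` the adjoint is
#' `(g - u (g . u)) / ||v||`, and for the activation `dS/dZ = Z / S`.
#' Where a norm guard fired the norm is a constant and the projection term
#' is dropped. Matches central finite differences to a relative error
#' below 1e-5. Like [sf_objective()], the result is computed in canonical
#' gene order and is bitwise invariant under gene permutations of `x`.
#'
#' @inheritParams sf_objective
#' @return The `d_in x t` matrix of partial derivatives of [sf_objective()]
#'   with respect to `y`.
#' @export
sf_gradient <- function(y, x) {
  check_sf_shapes(y, x)
  sf_gradient_canonical(y, x[, canonical_col_order(x), drop = FALSE])
}

sf_gradient_canonical <- function(y, x) {
  fw <- sf_forward(y, x)
  tdim <- ncol(y)
  m <- ncol(x)

  g_hat <- matrix(1, tdim, m)           # dJ/dS-hat
  # column-normalization adjoint: dJ/dS-tilde[, j]
  cproj <- colSums(g_hat * fw$s_hat)
  cproj[fw$cg$degenerate] <- 0
  g_row <- sweep(g_hat, 2L, fw$cg$norm, "/") -
    sweep(fw$s_hat, 2L, cproj / fw$cg$norm, "*")
  # row-normalization adjoint: dJ/dS[i, ]
  rproj <- rowSums(g_row * fw$s_row)
  rproj[fw$rg$degenerate] <- 0
  g_s <- g_row / fw$rg$norm - fw$s_row * (rproj / fw$rg$norm)
  # soft-absolute adjoint and linear map Z = Y^T X
  g_z <- g_s * fw$z / fw$s
  x %*% t(g_z)
}

#' Fit one sparse-filtering layer with L-BFGS
#'
#' Initializes the `d_in x t` filter matrix with i.i.d. standard-normal
#' draws from a seeded generator and minimizes [sf_objective()] with
#' `stats::optim(method = "L-BFGS-B")` using the analytic [sf_gradient()].
#' The fit is fully reproducible from `(x, n_filters, seed, max_iter,
#' pgtol)`; different seeds give different random initializations and hence
#' generally different optima.
#'
#' @param x Input matrix, `d_in x m` (layer 1 receives the standardized
#'   samples-x-genes matrix; deeper layers the normalized previous output).
#' @param n_filters Number of learned samples `t` (columns of the filter).
#' @param seed Integer seed for the filter initialization.
#' @param max_iter Maximum number of L-BFGS iterations (default 200).
#' @param pgtol Projected-gradient tolerance for convergence (default 1e-5).
#' @param history Number of L-BFGS correction pairs kept (default 10).
#' @return An object of class `sf_layer`: a list with `filter` (the optimal
#'   `Y`), `distribution` (the optimal sample distribution
#'   `S = soft_abs(Y^T X)`, `t x m`, strictly positive), `objective_trace`
#'   (monotone sequence of improving objective evaluations, initial value
#'   first), `objective_evals` (every objective evaluation, line-search
#'   points included), `value` (final objective), `converged`, `iterations`,
#'   `seed` and the input dimensions.
#' @export
fit_sf_layer <- function(x, n_filters, seed, max_iter = 200L, pgtol = 1e-5,
                         history = 10L) {
  stopifnot(is.matrix(x), is.numeric(x), all(is.finite(x)))
  if (ncol(x) < 2L) stop("input must have at least 2 columns (genes)")
  n_filters <- as.integer(n_filters)
  if (n_filters < 1L) stop("n_filters must be a positive integer")
  d_in <- nrow(x)

  y0 <- local_seed(seed,
                   matrix(rnorm(d_in * n_filters), d_in, n_filters))

  # optimize against the canonically ordered gene columns, so the whole
  # L-BFGS path is bitwise invariant to the input's gene order
  xc <- x[, canonical_col_order(x), drop = FALSE]

  state <- new.env(parent = emptyenv())
  state$evals <- numeric(0L)
  state$trace <- numeric(0L)

  fn <- function(par) {
    y <- matrix(par, d_in, n_filters)
    j <- sf_objective_canonical(y, xc)
    if (!is.finite(j))
      stop("non-finite objective at evaluation ", length(state$evals) + 1L)
    state$evals <- c(state$evals, j)
    if (length(state$trace) == 0L || j <= state$trace[length(state$trace)])
      state$trace <- c(state$trace, j)
    j
  }
  gr <- function(par) {
    as.vector(sf_gradient_canonical(matrix(par, d_in, n_filters), xc))
  }

  res <- stats::optim(as.vector(y0), fn = fn, gr = gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = pgtol,
                                     lmm = history))
  y_opt <- matrix(res$par, d_in, n_filters)
  s_opt <- soft_abs(crossprod(y_opt, x))
  if (!is.null(colnames(x))) colnames(s_opt) <- colnames(x)

  structure(list(filter = y_opt,
                 distribution = s_opt,
                 objective_trace = state$trace,
                 objective_evals = state$evals,
                 value = res$value,
                 initial_value = state$evals[1L],
                 converged = res$convergence == 0L,
                 iterations = res$counts[["function"]],
                 seed = as.integer(seed),
                 d_in = d_in,
                 n_filters = n_filters,
                 n_genes = ncol(x)),
            class = "sf_layer")
}

#' @export
print.sf_layer <- function(x, ...) {
  cat(sprintf("sparse-filtering layer: %d x %d filter over %d genes\n",
              x$d_in, x$n_filters, x$n_genes))
  cat(sprintf("  objective %.6g -> %.6g in %d evaluations (%s)\n",
              x$initial_value, x$value, length(x$objective_evals),
              if (x$converged) "converged" else "iteration limit"))
  invisible(x)
}
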