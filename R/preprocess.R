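# Denominator offset for the standard deviation used in standardization:
# 1L gives the sample convention (n - 1), 0L the population convention.
# Single switch point by design.
.SD_DENOM_OFFSET <- 1L

#' Standardize each sample of an expression matrix
#'
#' Centers and scales every row (sample) of the matrix to zero mean and unit
#' standard deviation, eliminating per-sample scale effects before sparse
#' filtering: `X = (B - mean(B)) / std(B)` with the row-wise mean and
#' (sample, n-1 denominator) standard deviation.
#'
#' Constant rows have no scale information; their standard deviation is
#' treated as 1 so they map to all-zero rows, with a warning.
#'
#' @param x Numeric samples-x-genes matrix with dimnames.
#' @return A matrix of the same shape and dimnames; every non-constant row
#'   has mean 0 (within 1e-8) and standard deviation 1 (within 1e-6).
#' @examples
#' b <- rbind(s1 = c(1, 2, 3), s2 = c(10, 30, 20))
#' colnames(b) <- c("g1", "g2", "g3")
#' standardize_samples(b)
#' @export
standardize_samples <- function(x) {
  validate_expression(x)
  m <- ncol(x)
  # gene-axis reductions accumulate in sorted order (see canonical_sum) so
  # standardization is exactly equivariant under gene permutations
  mu <- canonical_rowsums(x) / m
  centered <- x - mu
  s <- sqrt(canonical_rowsums(centered^2) / (m - .SD_DENOM_OFFSET))
  const <- s < 1e-12
  if (any(const)) {
    warning(sum(const), " constant sample row(s) mapped to zeros: ",
            paste(utils::head(rownames(x)[const], 3L), collapse = ", "))
    s[const] <- 1
  }
  out <- centered / s
  dimnames(out) <- dimnames(x)
  out
}
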