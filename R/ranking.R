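#' Evaluating vector: per-gene column sums of a sample distribution
#'
#' Sums the (absolute) activities of all learned samples on each gene. The
#' entries of an optimized sample distribution are nonnegative by
#' construction, but absolute values are taken so the operation is safe on
#' arbitrary matrices. The more differentially expressed a gene is across
#' the learned sample space, the larger its entry.
#'
#' @param s Numeric `t x m` sample distribution matrix, gene ids as
#'   `colnames` if available.
#' @return A nonnegative numeric vector of length `m`, named by gene.
#' @examples
#' evaluating_vector(rbind(c(1, 2), c(3, 4)))  # 4 6
#' @export
evaluating_vector <- function(s) {
  stopifnot(is.matrix(s), is.numeric(s), all(is.finite(s)))
  colSums(abs(s))
}

#' Select the top-h characteristic genes
#'
#' Sorts genes by score in descending order and returns the first `h` as the
#' characteristic genes. Ties are broken by original gene position (stable
#' sort), so results are deterministic.
#'
#' @param scores Numeric score vector (the evaluating vector), named by gene
#'   unless `gene_ids` is given.
#' @param gene_ids Character vector of gene identifiers aligned with
#'   `scores`; defaults to `names(scores)`.
#' @param h Number of genes to keep, `1 <= h <= length(scores)`.
#' @return A tibble with `h` rows and columns `rank` (1..h), `gene_id`,
#'   `score` (non-increasing).
#' @examples
#' select_top_genes(c(g1 = 0.1, g2 = 0.9, g3 = 0.5), h = 2)
#' @export
select_top_genes <- function(scores, gene_ids = names(scores), h) {
  stopifnot(is.numeric(scores), all(is.finite(scores)))
  m <- length(scores)
  if (is.null(gene_ids)) stop("gene identifiers required (names or gene_ids)")
  if (length(gene_ids) != m)
    stop("gene_ids length (", length(gene_ids),
         ") must match scores length (", m, ")")
  h <- as.integer(h)
  if (h < 1L || h > m)
    stop("h must be between 1 and the number of genes (", m, "); got ", h)
  ord <- order(-scores, seq_len(m), method = "radix")[seq_len(h)]
  tibble::tibble(rank = seq_len(h),
                 gene_id = as.character(gene_ids[ord]),
                 score = unname(scores[ord]))
}
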