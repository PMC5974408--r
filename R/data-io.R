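#' Read a gene-expression matrix from delimited text
#'
#' Loads a delimited expression matrix with one identifier row and one
#' identifier column and returns it in the internal convention: a numeric
#' matrix with `n` samples in rows and `m` genes in columns, sample
#' identifiers as `rownames` and gene identifiers as `colnames`, regardless
#' of the on-disk orientation.
#'
#' Most public expression text files put genes in rows and samples in
#' columns, so that is the default orientation; it is transposed on load.
#'
#' @param path Path to a delimited text file. The first row holds identifiers
#'   for the columns, the first column identifiers for the rows.
#' @param orientation `"genes_in_rows"` (default) if file rows are genes, or
#'   `"samples_in_rows"` if file rows are samples.
#' @param delimiter Field separator (default tab).
#' @param missing Policy for missing cells: `"error"` (default) rejects the
#'   file; `"impute_mean"` replaces each missing value by the mean of its
#'   gene across the samples where it is observed.
#' @return A numeric `n x m` matrix (samples x genes) with unique dimnames.
#' @seealso [write_expression()], [standardize_samples()]
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            delimiter = "\t",
                            missing = c("error", "impute_mean")) {
  orientation <- match.arg(orientation)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("expression file not found: ", path)

  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || nrow(raw) < 1L)
    stop("expression file must have an identifier column plus data columns")
  row_ids <- raw[[1L]]
  col_ids <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])

  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  # cells that failed numeric conversion but were not a recognised NA token
  bad <- which(is.na(vals) & !is.na(cells) &
                 !(trimws(cells) %in% c("NA", "NaN", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]],
                 row_ids[bad[1L, 1L]], col_ids[bad[1L, 2L]]))
  }

  dimnames(vals) <- list(row_ids, col_ids)
  if (orientation == "genes_in_rows") vals <- t(vals)

  if (anyNA(vals)) {
    if (missing == "error") {
      idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value for sample '%s', gene '%s' (set missing = \"impute_mean\" to impute)",
                   rownames(vals)[idx[1L]], colnames(vals)[idx[2L]]))
    }
    for (j in which(colSums(is.na(vals)) > 0L)) {
      mu <- mean(vals[, j], na.rm = TRUE)
      if (is.nan(mu))
        stop("gene '", colnames(vals)[j], "' has no observed values to impute from")
      vals[is.na(vals[, j]), j] <- mu
    }
  }
  validate_expression(vals)
  vals
}

#' Write a gene-expression matrix to delimited text
#'
#' Values are serialized with 17 significant digits so that a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param x Numeric samples-x-genes matrix with dimnames, as returned by
#'   [read_expression()] or [simulate_expression()].
#' @param path Output file path.
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path,
                             orientation = c("genes_in_rows", "samples_in_rows"),
                             delimiter = "\t") {
  orientation <- match.arg(orientation)
  validate_expression(x)
  out <- if (orientation == "genes_in_rows") t(x) else x
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(c("id", colnames(out)), collapse = delimiter)
  body <- vapply(seq_len(nrow(out)), function(i) {
    paste(c(rownames(out)[i],
            formatC(out[i, ], format = "g", digits = 17, width = -1)),
          collapse = delimiter)
  }, character(1L))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (samples x genes)")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("expression matrix needs at least 2 samples and 2 genes; got ",
         nrow(x), " x ", ncol(x))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry sample and gene identifiers as dimnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifier: ",
         rownames(x)[duplicated(rownames(x))][1L])
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene identifier: ",
         colnames(x)[duplicated(colnames(x))][1L])
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  invisible(x)
}

#' Write a ranked-gene table to TSV
#'
#' Emits a tab-separated file with header `rank`, `gene_id`, `score`.
#' Scores are printed with 6 significant digits; byte output is
#' deterministic for a fixed table.
#'
#' @param ranking A tibble/data frame with columns `rank`, `gene_id`,
#'   `score`, as produced by [select_top_genes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  validate_ranking(ranking)
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c("rank\tgene_id\tscore",
             if (nrow(ranking) > 0L)
               sprintf("%d\t%s\t%s", as.integer(ranking$rank), ranking$gene_id,
                       formatC(ranking$score, format = "g", digits = 6,
                               width = -1)))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a ranked-gene table written by [write_ranking()]
#'
#' @param path Path to a ranking TSV.
#' @return A tibble with columns `rank` (integer), `gene_id` (character) and
#'   `score` (double).
#' @export
read_ranking <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "numeric"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  validate_ranking(out)
  out
}

validate_ranking <- function(ranking) {
  need <- c("rank", "gene_id", "score")
  if (!is.data.frame(ranking) || !all(need %in% names(ranking)))
    stop("ranking must be a data frame with columns rank, gene_id, score")
  h <- nrow(ranking)
  if (h > 0L) {
    if (!identical(as.integer(ranking$rank), seq_len(h)))
      stop("ranks must be consecutive 1..", h)
    if (any(diff(ranking$score) > 0))
      stop("scores must be non-increasing with rank")
    if (any(ranking$score < 0))
      stop("scores must be nonnegative")
    if (anyDuplicated(ranking$gene_id))
      stop("duplicate gene_id in ranking")
  }
  invisible(ranking)
}
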