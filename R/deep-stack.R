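#' Inter-layer normalization
#'
#' Normalizes a layer's output sample distribution by rows and then by
#' columns with the L2 norm before it is fed to the next layer, so that
#' every learned sample contributes equally and every gene column lies on
#' the unit L2 ball.
#'
#' @param s Numeric matrix (a layer's `t x m` sample distribution).
#' @return A matrix of the same shape whose columns have unit L2 norm.
#' @export
interlayer_normalize <- function(s) {
  l2_normalize_cols(l2_normalize_rows(s))
}

#' Fit a deep sparse-filtering gene-selection model
#'
#' Greedy layer-wise training: layer 1 is fitted on the standardized
#' samples-x-genes matrix; each deeper layer is fitted on the
#' [interlayer_normalize()]d sample distribution of the previous layer.
#' There is no joint fine-tuning across layers. The gene axis is preserved
#' throughout, so the final layer's `t_k x m` distribution scores the
#' original genes.
#'
#' Per-layer filter initializations draw from seeds `seed + 1, ...,
#' seed + k`, so adding a layer never perturbs the training of earlier
#' layers and the whole stack is reproducible from its arguments. Because
#' the initialization is random, runs with different seeds generally reach
#' different (locally optimal) filters.
#'
#' @param x Standardized expression matrix (`n` samples x `m` genes), e.g.
#'   from [standardize_samples()].
#' @param n_layers Number of stacked layers `k` (default 3).
#' @param n_filters Learned samples per layer: a single integer applied to
#'   every layer (default 200) or a vector of length `n_layers`.
#' @param seed Master integer seed.
#' @inheritParams fit_sf_layer
#' @return An object of class `sldsf_fit` with elements `layers` (list of
#'   [fit_sf_layer()] results), `final_distribution` (the last layer's
#'   strictly positive `t_k x m` distribution), `scores` (the evaluating
#'   vector, see [evaluating_vector()]), `n_layers`, `layer_sizes`, `seed`,
#'   `gene_ids`, `sample_ids`.
#' @examples
#' sim <- simulate_expression(n_samples = 10, n_genes = 40, n_de = 4,
#'                            seed = 1)
#' fit <- sim$expression |> standardize_samples() |>
#'   sldsf(n_layers = 2, n_filters = 4, seed = 1, max_iter = 50)
#' tidy(fit)
#' @export
sldsf <- function(x, n_layers = 3L, n_filters = 200L, seed = 1L,
                  max_iter = 200L, pgtol = 1e-5) {
  stopifnot(is.matrix(x), is.numeric(x))
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L) stop("n_layers must be >= 1")
  layer_sizes <- as.integer(n_filters)
  if (length(layer_sizes) == 1L) layer_sizes <- rep(layer_sizes, n_layers)
  if (length(layer_sizes) != n_layers)
    stop("n_filters must have length 1 or n_layers (", n_layers,
         "); got length ", length(layer_sizes))
  if (any(layer_sizes < 1L)) stop("all layer sizes must be >= 1")

  layers <- vector("list", n_layers)
  input <- x
  for (i in seq_len(n_layers)) {
    layers[[i]] <- fit_sf_layer(input, layer_sizes[i], seed = seed + i,
                                max_iter = max_iter, pgtol = pgtol)
    if (i < n_layers) input <- interlayer_normalize(layers[[i]]$distribution)
  }
  final <- layers[[n_layers]]$distribution

  structure(list(layers = layers,
                 final_distribution = final,
                 scores = evaluating_vector(final),
                 n_layers = n_layers,
                 layer_sizes = layer_sizes,
                 seed = as.integer(seed),
                 max_iter = as.integer(max_iter),
                 pgtol = pgtol,
                 gene_ids = colnames(x),
                 sample_ids = rownames(x)),
            class = "sldsf_fit")
}

#' @export
print.sldsf_fit <- function(x, ...) {
  cat(sprintf("SLDSF fit: %d layer(s) [%s] over %d samples x %d genes, seed %d\n",
              x$n_layers, paste(x$layer_sizes, collapse = ", "),
              length(x$sample_ids) %||% NA_integer_,
              ncol(x$final_distribution), x$seed))
  obj <- vapply(x$layers, `[[`, numeric(1L), "value")
  cat("  final layer objectives:", paste(signif(obj, 6), collapse = ", "), "\n")
  cat("  top genes:",
      paste(utils::head(names(sort(x$scores, decreasing = TRUE)), 5L),
            collapse = ", "), "...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy an SLDSF fit into a per-gene score table
#'
#' @param x An `sldsf_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per gene: `gene_id`, `score` (evaluating
#'   vector entry) and `rank` (1 = highest score; ties broken by original
#'   gene order), sorted by rank.
#' @method tidy sldsf_fit
#' @export
tidy.sldsf_fit <- function(x, ...) {
  select_top_genes(x$scores, h = length(x$scores))
}

#' One-row summary of an SLDSF fit
#'
#' @param x An `sldsf_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: layer count and sizes, the final objective of
#'   the last layer, the total number of objective evaluations, whether all
#'   layers converged, and the seed.
#' @method glance sldsf_fit
#' @export
glance.sldsf_fit <- function(x, ...) {
  tibble::tibble(
    n_layers = x$n_layers,
    layer_sizes = paste(x$layer_sizes, collapse = ","),
    n_genes = ncol(x$final_distribution),
    final_objective = x$layers[[x$n_layers]]$value,
    total_evaluations = sum(vapply(x$layers, function(l)
      length(l$objective_evals), integer(1L))),
    all_converged = all(vapply(x$layers, `[[`, logical(1L), "converged")),
    seed = x$seed
  )
}

#' Plot per-layer objective traces of an SLDSF fit
#'
#' @param object An `sldsf_fit` object.
#' @param ... Unused.
#' @return A ggplot of the monotone objective trace of every layer against
#'   the (accepted) evaluation index, faceted by layer.
#' @method autoplot sldsf_fit
#' @export
autoplot.sldsf_fit <- function(object, ...) {
  df <- purrr::imap_dfr(object$layers, function(l, i) {
    tibble::tibble(layer = factor(paste("layer", i)),
                   step = seq_along(l$objective_trace),
                   objective = l$objective_trace)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~layer, scales = "free") +
    ggplot2::labs(x = "accepted objective evaluation",
                  y = "sparsity objective J",
                  title = "Layer-wise sparse-filtering descent")
}

#' Serialize an SLDSF model to a directory
#'
#' Writes one delimited matrix file per layer filter, the final sample
#' distribution, and a key-value `manifest.txt` with the configuration
#' (layer count, sizes, seed, optimizer settings). All matrices use 17
#' significant digits so [load_sldsf()] reproduces them exactly.
#'
#' @param fit An `sldsf_fit` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_sldsf <- function(fit, dir) {
  stopifnot(inherits(fit, "sldsf_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(fit$n_layers)) {
    write_matrix_tsv(fit$layers[[i]]$filter,
                     file.path(dir, sprintf("layer_%02d_filter.tsv", i)))
  }
  write_matrix_tsv(fit$final_distribution,
                   file.path(dir, "final_distribution.tsv"))
  write_manifest(list(n_layers = fit$n_layers,
                      layer_sizes = paste(fit$layer_sizes, collapse = ","),
                      seed = fit$seed,
                      max_iter = fit$max_iter,
                      pgtol = fit$pgtol,
                      gene_ids = paste(fit$gene_ids, collapse = ","),
                      package_version = as.character(utils::packageVersion("sldsf"))),
                 file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Load an SLDSF model serialized by [save_sldsf()]
#'
#' Restores the per-layer filters, the final distribution and the
#' configuration. Objective traces are not persisted.
#'
#' @param dir Directory written by [save_sldsf()].
#' @return A list of class `sldsf_model` with `filters`, the exact
#'   `final_distribution`, `scores`, `n_layers`, `layer_sizes`, `seed`,
#'   `max_iter`, `pgtol` and `gene_ids`.
#' @export
load_sldsf <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.txt"))
  k <- as.integer(man$n_layers)
  filters <- lapply(seq_len(k), function(i)
    read_matrix_tsv(file.path(dir, sprintf("layer_%02d_filter.tsv", i))))
  final <- read_matrix_tsv(file.path(dir, "final_distribution.tsv"))
  structure(list(filters = filters,
                 final_distribution = final,
                 scores = evaluating_vector(final),
                 n_layers = k,
                 layer_sizes = as.integer(strsplit(man$layer_sizes, ",")[[1L]]),
                 seed = as.integer(man$seed),
                 max_iter = as.integer(man$max_iter),
                 pgtol = as.numeric(man$pgtol),
                 gene_ids = strsplit(man$gene_ids, ",")[[1L]]),
            class = "sldsf_model")
}

# Plain numeric-matrix TSV (no identifier semantics; full precision).
write_matrix_tsv <- function(m, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- vapply(seq_len(nrow(m)), function(i)
    paste(formatC(m[i, ], format = "g", digits = 17, width = -1),
          collapse = "\t"), character(1L))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write a key-value run manifest
#'
#' @param fields Named list of scalar values.
#' @param path Output path; one `key=value` line per field.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fields, path) {
  stopifnot(is.list(fields), !is.null(names(fields)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(names(fields), "=",
                    vapply(fields, as.character, character(1L))),
             con, sep = "\n")
  invisible(path)
}

#' Read a key-value manifest written by [write_manifest()]
#'
#' @param path Manifest path.
#' @return Named list of character values.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0L)) stop("malformed manifest line: ", lines[which(eq < 0L)[1L]])
  stats::setNames(as.list(substring(lines, eq + 1L)),
                  substring(lines, 1L, eq - 1L))
}
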