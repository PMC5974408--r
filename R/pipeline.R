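#' End-to-end characteristic gene selection from a file
#'
#' Reads an expression matrix, standardizes each sample, fits an SLDSF
#' stack, computes the evaluating vector, writes the top-`h` ranking as TSV
#' and a key-value run manifest alongside it. Re-running with the same
#' manifest settings reproduces the outputs bitwise.
#'
#' Defaults follow the method's reported best configuration: 3 layers of
#' 200 learned samples, 100 selected genes.
#'
#' @inheritParams read_expression
#' @param input Path to the expression matrix file.
#' @param output Path for the ranking TSV; the manifest is written to
#'   `paste0(output, ".manifest")`.
#' @param n_layers,n_filters,seed,max_iter Stack settings, see [sldsf()].
#' @param h Number of genes to select (default 100).
#' @param model_dir Optional directory to serialize the fitted model into
#'   via [save_sldsf()].
#' @param quiet Suppress per-layer progress messages (default FALSE).
#' @return The ranking tibble, invisibly, with the fit attached as
#'   attribute `"fit"`.
#' @export
run_gene_selection <- function(input, output,
                               orientation = c("genes_in_rows",
                                               "samples_in_rows"),
                               delimiter = "\t",
                               n_layers = 3L, n_filters = 200L,
                               h = 100L, seed = 1L, max_iter = 200L,
                               model_dir = NULL, quiet = FALSE) {
  orientation <- match.arg(orientation)
  say <- function(...) if (!quiet) message(...)

  x <- tryCatch(read_expression(input, orientation = orientation,
                                delimiter = delimiter),
                error = function(e) stop("read stage: ",
                                         conditionMessage(e), call. = FALSE))
  h <- as.integer(h)
  if (h < 1L || h > ncol(x))
    stop("argument stage: h (", h, ") must be between 1 and the gene count (",
         ncol(x), ")", call. = FALSE)
  say(sprintf("loaded %d samples x %d genes from %s", nrow(x), ncol(x), input))

  xs <- standardize_samples(x)
  fit <- sldsf(xs, n_layers = n_layers, n_filters = n_filters, seed = seed,
               max_iter = max_iter)
  for (i in seq_len(fit$n_layers)) {
    l <- fit$layers[[i]]
    say(sprintf("layer %d: objective %.6g -> %.6g (%d evaluations, %s)",
                i, l$initial_value, l$value, length(l$objective_evals),
                if (l$converged) "converged" else "iteration limit"))
  }

  ranking <- select_top_genes(fit$scores, h = h)
  write_ranking(ranking, output)
  write_manifest(list(input = input,
                      output = output,
                      orientation = orientation,
                      delimiter = delimiter,
                      n_layers = fit$n_layers,
                      n_filters = paste(fit$layer_sizes, collapse = ","),
                      h = h,
                      seed = seed,
                      max_iter = as.integer(max_iter),
                      package_version =
                        as.character(utils::packageVersion("sldsf"))),
                 paste0(output, ".manifest"))
  if (!is.null(model_dir)) save_sldsf(fit, model_dir)
  say(sprintf("wrote %d-gene ranking to %s", h, output))
  invisible(structure(ranking, fit = fit))
}

#' Re-run a gene selection recorded in a manifest
#'
#' Reads a run manifest written by [run_gene_selection()] and replays the
#' selection with exactly the recorded settings, reproducing the ranking
#' file bitwise.
#'
#' @param manifest Path to a `.manifest` file.
#' @param output Optional override for the output path (default: the
#'   recorded one).
#' @param quiet Passed to [run_gene_selection()].
#' @return As [run_gene_selection()].
#' @export
rerun_from_manifest <- function(manifest, output = NULL, quiet = FALSE) {
  man <- read_manifest(manifest)
  sizes <- as.integer(strsplit(man$n_filters, ",")[[1L]])
  run_gene_selection(input = man$input,
                     output = output %||% man$output,
                     orientation = man$orientation,
                     delimiter = man$delimiter,
                     n_layers = as.integer(man$n_layers),
                     n_filters = sizes,
                     h = as.integer(man$h),
                     seed = as.integer(man$seed),
                     max_iter = as.integer(man$max_iter),
                     quiet = quiet)
}
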