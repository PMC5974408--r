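#' Simulate a two-class expression matrix with planted DE genes
#'
#' Generates the simplest data structure consistent with the premise of
#' characteristic-gene selection: a homogeneous Gaussian background in which
#' a small planted set of genes is differentially expressed between two
#' sample classes. Background entries are i.i.d. `Normal(0, noise_sd^2)`;
#' each planted gene receives an additive shift of `effect_size * noise_sd`
#' in class-1 samples only. Planted gene positions are drawn from the seeded
#' generator, so under `effect_size = 0` the planted set is exchangeable
#' with the background.
#'
#' @param n_samples Number of samples `n` (default 40).
#' @param n_genes Number of genes `m` (default 500).
#' @param n_de Number of planted differentially expressed genes
#'   (default 25; must not exceed `n_genes`).
#' @param class_fraction Fraction of samples in class 1, strictly between 0
#'   and 1 with both classes non-empty (default 0.5).
#' @param effect_size Mean shift of planted genes in class-1 samples, in
#'   units of `noise_sd` (default 3).
#' @param noise_sd Baseline noise standard deviation (default 1).
#' @param seed Integer seed; the same seed reproduces the matrix bitwise.
#' @return A list with `expression` (an `n x m` matrix, sample ids
#'   `S001...`, gene ids `G0001...`), `de_genes` (character vector of the
#'   `n_de` planted gene ids), and `classes` (integer 0/1 vector named by
#'   sample).
#' @export
simulate_expression <- function(n_samples = 40L, n_genes = 500L, n_de = 25L,
                                class_fraction = 0.5, effect_size = 3,
                                noise_sd = 1, seed = 1L) {
  n <- as.integer(n_samples); m <- as.integer(n_genes)
  n_de <- as.integer(n_de)
  if (n < 2L || m < 2L) stop("need at least 2 samples and 2 genes")
  if (n_de < 0L || n_de > m) stop("n_de must lie in [0, n_genes]")
  if (!(class_fraction > 0 && class_fraction < 1))
    stop("class_fraction must be strictly between 0 and 1")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  n1 <- round(class_fraction * n)
  if (n1 < 1L || n1 > n - 1L)
    stop("class_fraction leaves an empty class for n_samples = ", n)

  gene_ids <- sprintf(paste0("G%0", max(4L, nchar(m)), "d"), seq_len(m))
  sample_ids <- sprintf(paste0("S%0", max(3L, nchar(n)), "d"), seq_len(n))
  classes <- stats::setNames(rep(c(1L, 0L), c(n1, n - n1)), sample_ids)

  out <- local_seed(seed, {
    de_idx <- sort(sample.int(m, n_de))
    x <- matrix(rnorm(n * m, mean = 0, sd = noise_sd), n, m,
                dimnames = list(sample_ids, gene_ids))
    if (n_de > 0L)
      x[classes == 1L, de_idx] <- x[classes == 1L, de_idx] +
        effect_size * noise_sd
    list(x = x, de_idx = de_idx)
  })

  list(expression = out$x,
       de_genes = gene_ids[out$de_idx],
       classes = classes)
}

#' Precision and recall of planted-gene recovery
#'
#' Scores how well the top of a ranking recovers a planted gene set:
#' `precision = |top-h intersect planted| / h` and
#' `recall = |top-h intersect planted| / n_planted`.
#'
#' @param ranking A ranked-gene tibble from [select_top_genes()].
#' @param de_genes Character vector of planted (true) gene ids.
#' @param h Cutoff; defaults to the full table. Must not exceed its rows.
#' @param gene_ids Optional universe of valid gene ids; if supplied, any
#'   ranking entry outside it is an error.
#' @return A one-row tibble: `h`, `n_hit`, `precision`, `recall`.
#' @export
recovery_metrics <- function(ranking, de_genes, h = nrow(ranking),
                             gene_ids = NULL) {
  validate_ranking(ranking)
  h <- as.integer(h)
  if (h < 1L || h > nrow(ranking))
    stop("h must be between 1 and the number of ranked genes (",
         nrow(ranking), ")")
  if (!is.null(gene_ids)) {
    unknown <- setdiff(ranking$gene_id, gene_ids)
    if (length(unknown) > 0L)
      stop("unknown gene id in ranking: ", unknown[1L])
  }
  top <- ranking$gene_id[seq_len(h)]
  n_hit <- length(intersect(top, de_genes))
  tibble::tibble(h = h, n_hit = n_hit,
                 precision = n_hit / h,
                 recall = n_hit / length(de_genes))
}

#' Benchmark planted-gene recovery over seeds
#'
#' For each seed: simulate a two-class matrix with planted DE genes,
#' standardize, fit an SLDSF stack, rank genes by the evaluating vector and
#' measure top-`h` precision/recall against the planted set.
#'
#' @inheritParams simulate_expression
#' @param seeds Integer vector of simulation/fit seeds (one run per seed).
#' @param n_layers,n_filters,max_iter SLDSF stack settings (see [sldsf()]).
#' @param h Ranking cutoff; defaults to `n_de`.
#' @return A tibble with one row per seed: `seed`, `h`, `n_hit`,
#'   `precision`, `recall`, `final_objective`.
#' @examples
#' \donttest{
#' bench <- benchmark_recovery(seeds = 1:3, n_layers = 2, n_filters = 10)
#' stats::median(bench$precision)
#' }
#' @export
benchmark_recovery <- function(seeds = 1:10, n_samples = 40L, n_genes = 500L,
                               n_de = 25L, class_fraction = 0.5,
                               effect_size = 3, noise_sd = 1,
                               n_layers = 2L, n_filters = 20L,
                               h = n_de, max_iter = 200L) {
  purrr::map_dfr(seeds, function(s) {
    sim <- simulate_expression(n_samples = n_samples, n_genes = n_genes,
                               n_de = n_de, class_fraction = class_fraction,
                               effect_size = effect_size, noise_sd = noise_sd,
                               seed = s)
    fit <- sldsf(standardize_samples(sim$expression), n_layers = n_layers,
                 n_filters = n_filters, seed = s, max_iter = max_iter)
    ranking <- select_top_genes(fit$scores, h = h)
    metrics <- recovery_metrics(ranking, sim$de_genes, h = h,
                                gene_ids = colnames(sim$expression))
    dplyr::bind_cols(tibble::tibble(seed = s), metrics,
                     tibble::tibble(final_objective =
                                      fit$layers[[fit$n_layers]]$value))
  })
}
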