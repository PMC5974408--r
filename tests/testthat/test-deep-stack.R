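test_that("inter-layer normalization yields unit column norms", {
  one_row <- matrix(runif(6) + 0.5, 1, 6)
  expect_equal(interlayer_normalize(one_row), matrix(1, 1, 6))
  # idempotent in the single-row case
  expect_equal(interlayer_normalize(interlayer_normalize(one_row)),
               interlayer_normalize(one_row))

  m <- abs(rand_matrix(4, 9, seed = 5)) + 0.05
  out <- interlayer_normalize(m)
  expect_lt(max(abs(sqrt(colSums(out^2)) - 1)), 1e-12)
  expect_equal(dim(out), dim(m))
})

test_that("a one-layer stack reduces exactly to a single layer fit", {
  x <- rand_matrix(6, 15, seed = 8)
  colnames(x) <- paste0("g", 1:15)
  rownames(x) <- paste0("s", 1:6)
  stack <- sldsf(x, n_layers = 1, n_filters = 4, seed = 10, max_iter = 60)
  single <- fit_sf_layer(x, 4, seed = 11, max_iter = 60)  # seed + layer index
  expect_identical(stack$final_distribution, single$distribution)
  expect_identical(stack$layers[[1]]$filter, single$filter)
})

test_that("stack shapes chain through layer sizes and m is preserved", {
  x <- rand_matrix(7, 12, seed = 13)
  colnames(x) <- paste0("g", 1:12)
  fit <- sldsf(x, n_layers = 3, n_filters = c(5, 4, 3), seed = 1,
               max_iter = 40)
  expect_equal(fit$layer_sizes, c(5L, 4L, 3L))
  expect_equal(dim(fit$layers[[1]]$filter), c(7L, 5L))
  expect_equal(dim(fit$layers[[2]]$filter), c(5L, 4L))
  expect_equal(dim(fit$layers[[3]]$filter), c(4L, 3L))
  for (l in fit$layers) expect_equal(l$n_genes, 12L)
  expect_equal(dim(fit$final_distribution), c(3L, 12L))
  expect_true(all(fit$final_distribution >= 1e-4))

  expect_error(sldsf(x, n_layers = 2, n_filters = c(3, 3, 3)), "length")
})

test_that("the whole stack is reproducible and gene-permutation equivariant", {
  x <- standardize_samples(simulate_expression(n_samples = 12, n_genes = 60,
                                               n_de = 5, seed = 2)$expression)
  f1 <- sldsf(x, n_layers = 2, n_filters = 5, seed = 7, max_iter = 80)
  f2 <- sldsf(x, n_layers = 2, n_filters = 5, seed = 7, max_iter = 80)
  expect_identical(f1$final_distribution, f2$final_distribution)

  p <- sample(ncol(x))
  fp <- sldsf(x[, p], n_layers = 2, n_filters = 5, seed = 7, max_iter = 80)
  expect_identical(unname(fp$final_distribution),
                   unname(f1$final_distribution[, p]))
  expect_identical(unname(fp$scores), unname(f1$scores[p]))
})

test_that("model serialization round-trips filters and distribution exactly", {
  x <- standardize_samples(toy_expression(n = 6, m = 20, seed = 9))
  fit <- sldsf(x, n_layers = 2, n_filters = 3, seed = 4, max_iter = 50)
  dir <- withr::local_tempdir()
  save_sldsf(fit, dir)
  back <- load_sldsf(dir)
  expect_identical(back$n_layers, fit$n_layers)
  expect_identical(back$layer_sizes, fit$layer_sizes)
  expect_identical(back$seed, fit$seed)
  for (i in 1:2)
    expect_identical(back$filters[[i]], unname(fit$layers[[i]]$filter))
  expect_identical(unname(back$final_distribution),
                   unname(fit$final_distribution))
  expect_equal(unname(back$scores), unname(fit$scores))
  expect_identical(back$gene_ids, fit$gene_ids)
})

test_that("tidy, glance and autoplot summarize a fit", {
  x <- standardize_samples(toy_expression(n = 5, m = 12, seed = 14))
  fit <- sldsf(x, n_layers = 2, n_filters = 3, seed = 6, max_iter = 40)

  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12L)
  expect_identical(td$rank, 1:12)
  expect_true(all(diff(td$score) <= 0))
  expect_setequal(td$gene_id, colnames(x))

  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_identical(gl$n_layers, 2L)
  expect_equal(gl$final_objective, fit$layers[[2]]$value)

  expect_s3_class(autoplot(fit), "ggplot")
})
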