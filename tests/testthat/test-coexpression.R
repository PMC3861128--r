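test_that("row normalization scales to unit sum of squares and is idempotent", {
  expect_equal(as.numeric(normalize_rows(
    data.frame(gene_id = "g", c1 = 3, c2 = 4))[1, -1]), c(0.6, 0.8))

  ex <- simulate_expression_matrix(c(72, 72), n_conditions = 21, seed = 1)
  norm1 <- normalize_rows(ex$expression)
  ss <- rowSums(as.matrix(norm1[, -1])^2)
  expect_equal(unname(ss), rep(1, nrow(norm1)), tolerance = 1e-9)

  norm2 <- normalize_rows(norm1)
  expect_equal(as.matrix(norm2[, -1]), as.matrix(norm1[, -1]), tolerance = 1e-12)
  expect_equal(attr(norm2, "scale_factors")$scale_factor,
               rep(1, nrow(norm1)), tolerance = 1e-9)

  # all-zero rows are reported and excluded
  withzero <- data.frame(gene_id = c("a", "z"), c1 = c(1, 0), c2 = c(2, 0))
  expect_warning(out <- normalize_rows(withzero), "all-zero")
  expect_equal(out$gene_id, "a")
  expect_equal(attr(out, "dropped"), "z")
})

test_that("centered Pearson has the textbook values and invariances", {
  x <- c(1, 2, 3, 4)
  expect_equal(centered_pearson(x, 2 * x + 3), 1)
  expect_equal(centered_pearson(x, -x), -1)
  expect_equal(centered_pearson(x, c(1, 3, 2, 4)), 0.8)
  # positive affine invariance
  y <- rnorm(10)
  x10 <- rnorm(10)
  expect_equal(centered_pearson(x10, y), centered_pearson(5 * x10 + 2, y))
  expect_error(centered_pearson(x, rep(1, 4)), "variance")
})

test_that("the SOM seeding is deterministic and separates clean clusters", {
  ex <- simulate_expression_matrix(c(10, 10), r_within = 0.95, seed = 2)
  en <- normalize_rows(ex$expression)
  s1 <- som_seed(en, k = 2, steps = 1500, seed = 3)
  s2 <- som_seed(en, k = 2, steps = 1500, seed = 3)
  expect_identical(s1, s2)

  # two well-separated clusters recovered up to label swap in most seeds
  hits <- vapply(1:30, function(s) {
    ex <- simulate_expression_matrix(c(10, 10), r_within = 0.95, seed = s)
    en <- normalize_rows(ex$expression)
    node <- som_seed(en, k = 2, steps = 1500, seed = s + 100)$node
    agree <- mean(node == ex$labels$cluster)
    max(agree, 1 - agree) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # capacity case: k equal to the gene count runs and assigns valid nodes
  full <- som_seed(en, k = 20, steps = 500, seed = 1)
  expect_true(all(full$node %in% 1:20))
})

test_that("complete-linkage trees match a naive O(n^3) oracle", {
  for (s in 1:6) {
    set.seed(s)
    n <- 12
    mat <- matrix(rnorm(n * 10), nrow = n)
    expr <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%02d", 1:n)),
                             tibble::as_tibble(as.data.frame(mat)))
    cl <- hierarchical_cluster(expr)
    D <- 1 - cor(t(mat))
    ref <- bf_complete_linkage(D)
    for (k in 2:(n - 1)) {
      expect_true(same_partition(cutree(cl$hclust, k)[order(cl$gene_ids)],
                                 ref[[as.character(k)]][order(cl$gene_ids)]))
    }
    # merge heights are non-decreasing (complete linkage is monotone)
    expect_true(all(diff(cl$hclust$height) >= -1e-12))
  }
})

test_that("the nearest pair merges first", {
  # 3 profiles engineered so one pair has r ~ 0.9 and the rest ~ 0.1
  set.seed(7)
  base <- rnorm(21)
  x1 <- base + rnorm(21, 0, 0.3)
  x2 <- base + rnorm(21, 0, 0.3)
  x3 <- rnorm(21)
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = c("a", "b", "c")),
                           tibble::as_tibble(as.data.frame(rbind(x1, x2, x3))))
  cl <- hierarchical_cluster(expr)
  expect_true(same_partition(cutree(cl$hclust, 2), c(1, 1, 2)))
})

test_that("cut_and_score flags cohesive clusters and handles singletons", {
  ex <- simulate_expression_matrix(c(8, 8), r_within = 1, seed = 4)
  en <- normalize_rows(ex$expression)
  cl <- hierarchical_cluster(en)

  res <- cut_and_score(cl, k = 2)
  expect_equal(sort(res$clusters$n_genes), c(8, 8))
  expect_equal(res$clusters$cohesion, c(1, 1), tolerance = 1e-9)
  expect_true(all(res$clusters$highly_correlated))

  # k = n: all singletons, cohesion undefined
  res_n <- cut_and_score(cl, k = 16)
  expect_true(all(is.na(res_n$clusters$cohesion)))
  expect_equal(nrow(res_n$clusters), 16)
})

test_that("cluster recovery is invariant to input row order", {
  ex <- simulate_expression_matrix(c(8, 8, 8), r_within = 0.85, seed = 5)
  en <- normalize_rows(ex$expression)
  som <- som_seed(en, k = 5, steps = 1000, seed = 6)
  r1 <- cut_and_score(hierarchical_cluster(en, som = som), k = 3)

  perm <- sample(nrow(en))
  en_p <- en[perm, ]
  som_p <- som[perm, ]
  r2 <- cut_and_score(hierarchical_cluster(en_p, som = som_p), k = 3)

  j <- dplyr::inner_join(r1$labels, r2$labels, by = "gene_id")
  expect_true(same_partition(j$cluster.x, j$cluster.y))
})

test_that("planted blocks are recovered with high ARI (reduced-scale)", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:10, function(s) {
    ex <- simulate_expression_matrix(c(12, 12, 12, 12), n_conditions = 21,
                                     r_within = 0.8, seed = s)
    en <- normalize_rows(ex$expression)
    res <- cut_and_score(hierarchical_cluster(en), k = 4)
    mclust::adjustedRandIndex(res$labels$cluster, ex$labels$cluster)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})
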