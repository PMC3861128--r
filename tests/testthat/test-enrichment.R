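test_that("hypergeometric tail and EASE score match hand enumeration", {
  expect_equal(hypergeom_tail(0, 4, 5, 20), 1)
  expect_equal(hypergeom_tail(5, 5, 5, 5), 1)
  # C(4,3)C(16,2)/C(20,5) + C(4,4)C(16,1)/C(20,5)
  expect_equal(hypergeom_tail(3, 4, 5, 20), 0.0320, tolerance = 1e-3)
  expect_equal(ease_score(3, 4, 5, 20), 0.2487, tolerance = 1e-3)
  expect_equal(ease_score(1, 4, 5, 20), 1)
  expect_error(hypergeom_tail(6, 4, 5, 20), "infeasible")
})

test_that("scores agree with exhaustive enumeration over a feasible grid", {
  set.seed(1)
  for (N in c(6, 11, 17, 23, 30)) {
    for (rep in 1:40) {
      n <- sample.int(N, 1)
      K <- sample.int(N, 1)
      k <- sample.int(min(n, K) + 1, 1) - 1
      expect_equal(hypergeom_tail(k, K, n, N), bf_hyper_tail(k, K, n, N),
                   tolerance = 1e-12)
      expect_equal(ease_score(k, K, n, N), bf_hyper_tail(max(k - 1, 0), K, n, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("EASE is uniformly conservative and monotone in the overlap", {
  set.seed(2)
  for (i in 1:200) {
    N <- sample(5:60, 1); n <- sample.int(N, 1); K <- sample.int(N, 1)
    k <- sample.int(min(n, K) + 1, 1) - 1
    expect_gte(ease_score(k, K, n, N), hypergeom_tail(k, K, n, N))
  }
  # monotone non-increasing in k for fixed (K, n, N)
  ks <- 0:5
  ps <- ease_score(ks, 8, 6, 40)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("cluster enrichment reproduces the Count (%) arithmetic", {
  # a 14-gene cluster with 5 genes carrying the term prints 35.7%
  cluster_genes <- sprintf("c%02d", 1:14)
  background <- sprintf("b%02d", 1:86)
  universe <- c(cluster_genes, background)
  sets <- list(cation_channel = c(cluster_genes[1:5], background[1:3]),
               unrelated = background[10:40])
  ann <- annotation_table(sets, universe = universe)
  labels <- tibble::tibble(gene_id = cluster_genes, cluster = 1)
  res <- enrich_clusters(labels, ann, alpha = 0.05)
  hit <- res[res$term == "cation_channel", ]
  expect_equal(hit$k, 5L)
  expect_equal(round(hit$percent, 1), 35.7)
  expect_false("unrelated" %in% res$term) # absent from the cluster
  expect_true(all(res$ease_p >= res$fisher_p))
})

test_that("a strongly planted term is the cluster's top hit", {
  set.seed(3)
  top_hits <- vapply(1:60, function(s) {
    set.seed(s)
    universe <- sprintf("g%03d", 1:200)
    members <- universe[1:20]
    planted <- unique(c(sample(members, 10), sample(universe[-(1:20)], 5)))
    sets <- list(planted = planted)
    for (b in 1:8) sets[[paste0("bg", b)]] <- sample(universe, 25)
    ann <- annotation_table(sets, universe = universe)
    res <- enrich_clusters(tibble::tibble(gene_id = members, cluster = 1),
                           ann, alpha = 1)
    res$term[which.min(res$ease_p)] == "planted"
  }, logical(1))
  expect_gte(mean(top_hits), 0.95)
})

test_that("results are invariant to gene id relabeling and report stray genes", {
  universe <- sprintf("g%02d", 1:50)
  sets <- list(t1 = universe[1:10], t2 = universe[5:30])
  ann <- annotation_table(sets, universe = universe)
  labels <- tibble::tibble(gene_id = universe[1:12], cluster = 1)
  base <- enrich_clusters(labels, ann, alpha = 1)

  remap <- setNames(sprintf("X%02d", 1:50), universe)
  ann2 <- annotation_table(lapply(sets, function(s) unname(remap[s])),
                           universe = unname(remap))
  labels2 <- tibble::tibble(gene_id = unname(remap[labels$gene_id]), cluster = 1)
  rel <- enrich_clusters(labels2, ann2, alpha = 1)
  expect_equal(base$ease_p, rel$ease_p)
  expect_equal(base$k, rel$k)

  stray <- dplyr::bind_rows(labels,
                            tibble::tibble(gene_id = "not_in_universe", cluster = 1))
  expect_warning(res <- enrich_clusters(stray, ann, alpha = 1), "absent")
  expect_equal(res$n[1], 12L)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back[["alpha"]], sets$alpha)
  expect_equal(back[["beta"]], sets$beta)
})
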