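test_that("toy genomes respect their construction invariants and are deterministic", {
  g <- make_toy_genome(n_genes = 1, chrom_length = 10000, probe_spacing = 55, seed = 1)
  expect_equal(nrow(g$genes), 1)
  expect_true(abs(nrow(g$probes) - 181) < 15) # ~ chrom_length / spacing
  expect_equal(median(diff(g$probes$start)), 55, tolerance = 0.05)

  g2 <- make_toy_genome(50, 500000, seed = 7)
  expect_true(all(g2$genes$start >= 0 & g2$genes$end <= 500000))
  expect_true(all(diff(g2$probes$start) > 0))
  expect_true(all(g2$genes$end > g2$genes$start))

  expect_identical(make_toy_genome(10, 100000, seed = 42),
                   make_toy_genome(10, 100000, seed = 42))

  # over-dense layouts are rejected, not silently squeezed
  expect_error(make_toy_genome(100, 120000, seed = 1), "over-dense")
})

test_that("tiling simulation plants domains at the specified effect size", {
  g <- make_toy_genome(20, 200000, seed = 2)

  # no spiked genes: drug and control tracks differ only by noise
  sp0 <- spike_spec(width = 1000, effect = 1)
  sim0 <- simulate_tiling_experiment(g, sp0, noise_sd = 0.1, seed = 3)
  d0 <- difference_from_sim(sim0, "A")
  expect_lt(abs(mean(d0$value)), 0.02)

  # planted gene sets are recovered exactly in the ground truth
  sp <- spike_spec(shared = g$genes$gene_id[1:4], a_only = g$genes$gene_id[5:6],
                   b_only = g$genes$gene_id[7:8], width = 1000, effect = 1)
  sim <- simulate_tiling_experiment(g, sp, noise_sd = 0.3, seed = 4)
  expect_setequal(sim$truth$shared, g$genes$gene_id[1:4])
  domA <- dplyr::filter(sim$truth$domains, drug == "A")
  expect_setequal(domA$gene_id, g$genes$gene_id[1:6])

  # probe-averaged difference inside spiked domains ~ effect size
  d <- difference_from_sim(sim, "A")
  mid <- (d$start + d$end) / 2
  inside <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(domA))) {
    inside <- inside | (mid >= domA$start[i] & mid < domA$end[i])
  }
  n_in <- sum(inside)
  expect_gt(n_in, 50)
  expect_equal(mean(d$value[inside]), 1.0, tolerance = 4 * 0.3 / sqrt(n_in) + 0.02)

  # determinism
  sim_b <- simulate_tiling_experiment(g, sp, noise_sd = 0.3, seed = 4)
  expect_identical(sim$channels, sim_b$channels)

  # mean elevation converges to the effect as noise shrinks
  for (nsd in c(0.5, 0.1, 0.01)) {
    s <- simulate_tiling_experiment(g, sp, noise_sd = nsd, seed = 11)
    dd <- difference_from_sim(s, "A")
    expect_equal(mean(dd$value[inside]), 1.0,
                 tolerance = 4 * nsd / sqrt(n_in) + 0.02)
  }
})

test_that("expression simulation hits its correlation targets", {
  # noiseless limit: affine copies, pairwise r exactly 1
  ex1 <- simulate_expression_matrix(c(5, 5), r_within = 1, seed = 1)
  m <- as.matrix(ex1$expression[, -1])
  cors <- cor(t(m[1:5, ]))
  expect_equal(unname(cors[lower.tri(cors)]), rep(1, 10), tolerance = 1e-12)

  # shape follows the cluster sizes
  ex2 <- simulate_expression_matrix(c(67, 10, 5, 14), n_conditions = 21, seed = 2)
  expect_equal(dim(ex2$expression), c(96, 22))
  expect_equal(as.integer(table(ex2$labels$cluster)), c(67, 10, 5, 14))

  # orthogonal latent profiles: between-cluster r ~ 0 on average (Monte Carlo)
  between <- vapply(1:40, function(s) {
    ex <- simulate_expression_matrix(c(8, 8), r_within = 0.9, seed = s)
    mm <- as.matrix(ex$expression[, -1])
    cc <- cor(t(mm))
    mean(cc[1:8, 9:16])
  }, numeric(1))
  expect_lt(abs(mean(between)), 0.05)

  expect_identical(simulate_expression_matrix(c(4, 4), seed = 9),
                   simulate_expression_matrix(c(4, 4), seed = 9))
})

test_that("recovery simulation produces integral monotone counts at the true t50", {
  lines <- data.frame(line = c("a", "b"), t50_control = c(60, 55),
                      t50_exposed = c(40, 55))
  rec <- simulate_recovery_dataset(lines, n_vials = 3, flies_per_vial = 12,
                                   interval = 5, seed = 1)
  expect_true(all(rec$n_recovered == floor(rec$n_recovered)))
  expect_true(all(rec$n_recovered <= rec$n_total))
  by_vial <- split(rec, interaction(rec$line, rec$group, rec$vial))
  for (v in by_vial) {
    expect_true(all(diff(v$n_recovered[order(v$time_min)]) >= 0))
  }
  # the empirical t50 of a large pooled group sits near the target
  big <- simulate_recovery_dataset(data.frame(line = "x", t50_control = 60,
                                              t50_exposed = 60),
                                   n_vials = 20, flies_per_vial = 50, seed = 2)
  ctl <- dplyr::filter(big, group == "control")
  pooled <- dplyr::summarise(dplyr::group_by(ctl, time_min),
                             pct = 100 * sum(n_recovered) / sum(n_total))
  t50_emp <- min(pooled$time_min[pooled$pct >= 50])
  expect_lt(abs(t50_emp - 60), 5 + 1e-9)
})

test_that("qPCR simulation encodes fold changes in the Ct values", {
  # noiseless: fold 4 means the treated target Ct is exactly 2 cycles lower
  ct <- simulate_qpcr(data.frame(gene = "g", fold = 4), noise_sd = 0,
                      n_replicates = 3, seed = 1)
  trt <- ct$ct_target[ct$condition == "treated"]
  ctl <- ct$ct_target[ct$condition == "control"]
  expect_equal(unique(ctl) - unique(trt), 2)
  expect_equal(length(unique(ct$ct_reference)), 1)

  # fold 1, no noise: ddCt exactly zero
  ct1 <- simulate_qpcr(data.frame(gene = "g", fold = 1), noise_sd = 0, seed = 1)
  expect_equal(delta_delta_ct(ct1)$ddct, 0)

  # Monte Carlo: noisy estimates stay within 15% of truth on average
  folds <- vapply(1:30, function(s) {
    ct <- simulate_qpcr(data.frame(gene = "g", fold = 4), noise_sd = 0.2,
                        n_replicates = 8, seed = s)
    delta_delta_ct(ct)$fold
  }, numeric(1))
  expect_equal(mean(folds), 4, tolerance = 0.15)
  expect_gt(mean(abs(folds - 4) / 4 < 0.15), 0.6)
})
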