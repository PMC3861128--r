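test_that("scan_peaks handles constructed cases exactly", {
  zero <- random_track(100, seed = 1)
  zero$value <- rep(0, 100)
  expect_equal(nrow(scan_peaks(zero, threshold = 0.5)), 0)

  # one clean run of 6 probes at 2.0 in a zero background
  tr <- zero
  tr$value[41:46] <- 2
  pk <- scan_peaks(tr, threshold = 1, min_probes = 4)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, tr$start[41])
  expect_equal(pk$end, tr$end[46])
  expect_equal(pk$magnitude, 2)
  expect_equal(pk$summit, 2)
  expect_equal(pk$n_probes, 6L)

  # a run split by a wide gap is two peaks (or dropped below min_probes)
  tr2 <- zero
  tr2$value[c(10:13, 30:33)] <- 1.5
  pk2 <- scan_peaks(tr2, threshold = 1, min_probes = 4, max_gap = 150)
  expect_equal(nrow(pk2), 2)
})

test_that("scan_peaks matches an independent brute-force scanner on random tracks", {
  for (s in 1:25) {
    tr <- random_track(1000, noise_sd = 0.7, seed = s)
    thr <- runif(1, 0.5, 1.5)
    got <- scan_peaks(tr, thr, min_probes = 4, max_gap = 150)
    ref <- bf_scan_peaks(tr, thr, min_probes = 4, max_gap = 150)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref) > 0) {
      expect_equal(got$start, ref$start)
      expect_equal(got$end, ref$end)
      expect_equal(got$magnitude, ref$magnitude)
      expect_equal(got$n_probes, ref$n_probes)
    }
  }
})

test_that("raising the threshold never increases the peak count", {
  tr <- random_track(2000, noise_sd = 0.8, seed = 9)
  thresholds <- seq(0.3, 2, by = 0.1)
  counts <- vapply(thresholds, function(t) nrow(scan_peaks(tr, t, 3, 150)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("randomize_track conserves the value multiset and positions", {
  tr <- random_track(300, seed = 2)
  r <- randomize_track(tr, seed = 11)
  expect_equal(sort(r$value), sort(tr$value))
  expect_equal(r$start, tr$start)
  expect_equal(r$end, tr$end)

  const <- tr; const$value <- rep(1.5, 300)
  expect_equal(randomize_track(const, seed = 1)$value, const$value)

  rb <- randomize_track(tr, seed = 3, block = 10)
  expect_equal(sort(rb$value), sort(tr$value))
})

test_that("estimate_fdr matches exhaustive permutation enumeration on a tiny track", {
  # 6 probes, all 720 permutations enumerable
  st <- seq(0L, by = 55L, length.out = 6)
  vals <- c(0.1, 0.2, 1.1, 1.2, 1.3, 0.3)
  tr <- tibble::tibble(chrom = "c", start = st, end = st + 50L, value = vals)
  thresholds <- c(0.5, 1.0)

  perms <- all_perms(6)
  exact_null <- vapply(thresholds, function(t) {
    mean(apply(perms, 1, function(p) {
      ptr <- tr; ptr$value <- vals[p]
      nrow(scan_peaks(ptr, t, min_probes = 2, max_gap = 150))
    }))
  }, numeric(1))
  obs <- vapply(thresholds, function(t)
    nrow(scan_peaks(tr, t, min_probes = 2, max_gap = 150)), numeric(1))
  exact_fdr <- cummin(pmin(1, exact_null / pmax(1, obs)))

  curve <- estimate_fdr(tr, thresholds = thresholds, n_permutations = 4000,
                        min_probes = 2, max_gap = 150, seed = 5)
  expect_equal(curve$n_observed, as.integer(obs))
  expect_equal(curve$mean_null_count, exact_null, tolerance = 0.05)
  expect_equal(curve$fdr, exact_fdr, tolerance = 0.05)
})

test_that("the FDR curve is monotone and null tracks yield no confident threshold", {
  tr <- random_track(1500, noise_sd = 0.5, seed = 3)
  curve <- estimate_fdr(tr, n_permutations = 60, seed = 4)
  expect_true(all(diff(curve$fdr) <= 0))
  expect_true(all(curve$fdr >= 0 & curve$fdr <= 1))

  # pure-null tracks: select_peaks should essentially never fire
  fired <- 0
  for (s in 1:10) {
    ntr <- random_track(1000, noise_sd = 0.5, seed = 100 + s)
    cv <- estimate_fdr(ntr, n_permutations = 50, seed = 200 + s)
    pk <- select_peaks(ntr, cv)
    if (nrow(pk) > 0) fired <- fired + 1
  }
  expect_lte(fired, 1)
})

test_that("select_peaks applies the FDR and enrichment rules", {
  # no passing threshold: empty set with a recorded reason
  tr <- random_track(500, noise_sd = 0.5, seed = 6)
  curve <- estimate_fdr(tr, n_permutations = 40, seed = 7)
  pk <- select_peaks(tr, curve, fdr_cutoff = 0) # nothing can beat fdr < 0
  expect_equal(nrow(pk), 0)
  expect_match(attr(pk, "reason"), "FDR")

  # a single strong spike culminating at the track max scores exactly 1
  tr2 <- random_track(500, noise_sd = 0.1, seed = 8)
  tr2$value[200:209] <- 5
  cv2 <- estimate_fdr(tr2, n_permutations = 40, seed = 9)
  pk2 <- select_peaks(tr2, cv2)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$enrichment_score, 1)
  expect_lt(pk2$fdr, 0.05)
})

test_that("the permutation-calibrated caller controls the realized FDP with high recall", {
  # reduced-scale version of the simulation study (full run in the
  # acceptance suite): 3 datasets, 100 planted domains each
  fdps <- c(); recalls <- c()
  for (s in 1:3) {
    g <- make_toy_genome(100, 2e6, seed = s)
    sp <- spike_spec(a_only = g$genes$gene_id, width = 1000, effect = 1)
    sim <- simulate_tiling_experiment(g, sp, noise_sd = 0.5, seed = s + 50)
    tr <- difference_from_sim(sim, "A")
    cv <- estimate_fdr(tr, n_permutations = 100, seed = s + 99)
    pk <- select_peaks(tr, cv)
    dom <- sim$truth$domains
    tp <- vapply(seq_len(nrow(pk)), function(i)
      any(pk$start[i] < dom$end & pk$end[i] > dom$start), logical(1))
    hit <- vapply(seq_len(nrow(dom)), function(i)
      any(pk$start < dom$end[i] & pk$end > dom$start[i]), logical(1))
    fdps <- c(fdps, if (nrow(pk) > 0) mean(!tp) else 0)
    recalls <- c(recalls, mean(hit))
  }
  expect_lte(mean(fdps), 0.07)
  expect_gte(mean(recalls), 0.85)
})
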