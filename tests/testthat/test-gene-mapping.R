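test_that("gene regions are padded bidirectionally with clipping at zero", {
  g <- data.frame(gene_id = c("a", "b"), chrom = "c",
                  start = c(1000, 100), end = c(2000, 300),
                  strand = c("+", "-"))
  ext <- extend_gene_regions(g, pad = 500)
  expect_equal(ext$query_start, c(500, 0))
  expect_equal(ext$query_end, c(2500, 800))

  # strand does not change the padding
  flip <- g; flip$strand <- c("-", "+")
  expect_equal(extend_gene_regions(flip, 500)$query_start, ext$query_start)
})

test_that("the 500-bp boundary cases assign and reject exactly", {
  gene <- data.frame(gene_id = "g1", chrom = "c", start = 1000, end = 2000)
  near <- data.frame(chrom = "c", start = 2400, end = 2550, magnitude = 1)
  far <- data.frame(chrom = "c", start = 2600, end = 2700, magnitude = 1)

  a_near <- assign_peaks(near, gene)
  expect_equal(a_near$gene_id, "g1")
  expect_equal(a_near$distance, 400)

  a_far <- assign_peaks(far, gene)
  expect_true(is.na(a_far$gene_id))

  # overlap means distance zero
  over <- data.frame(chrom = "c", start = 1500, end = 1700, magnitude = 1)
  expect_equal(assign_peaks(over, gene)$distance, 0)
})

test_that("assign_peaks matches a brute-force all-pairs scan on random layouts", {
  for (s in 1:10) {
    set.seed(s)
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:60), chrom = "c",
      start = sort(sample.int(500000, 60)))
    genes$end <- genes$start + sample(500:5000, 60, replace = TRUE)
    peaks <- tibble::tibble(chrom = "c",
                            start = sort(sample.int(500000, 100)))
    peaks$end <- peaks$start + sample(100:2000, 100, replace = TRUE)
    peaks$magnitude <- runif(100, 0.5, 3)

    got <- assign_peaks(peaks, genes)
    ref <- bf_assign(peaks, genes)
    got_key <- paste(got$peak_id, got$gene_id, got$distance)
    ref_key <- paste(ref$peak_id, ref$gene_id, ref$distance)
    expect_setequal(got_key, ref_key)
  }
})

test_that("assignment is invariant under gene relabeling and strand flips", {
  set.seed(3)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), chrom = "c",
                          start = sort(sample.int(100000, 20)),
                          strand = sample(c("+", "-"), 20, TRUE))
  genes$end <- genes$start + 2000
  peaks <- tibble::tibble(chrom = "c", start = sort(sample.int(100000, 30)))
  peaks$end <- peaks$start + 300
  peaks$magnitude <- runif(30, 1, 2)

  base <- assign_peaks(peaks, genes)
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  expect_equal(assign_peaks(peaks, flipped)$gene_id, base$gene_id)

  relabeled <- genes
  relabeled$gene_id <- paste0("X_", genes$gene_id)
  expect_equal(assign_peaks(peaks, relabeled)$gene_id,
               ifelse(is.na(base$gene_id), NA, paste0("X_", base$gene_id)))
})

test_that("cohorts take the best peak per gene and rank deterministically", {
  asn <- tibble::tibble(
    peak_id = 1:4, chrom = "c", peak_start = c(1, 2, 3, 4) * 100,
    peak_end = c(1, 2, 3, 4) * 100 + 50,
    magnitude = c(1.2, 2.0, 1.5, NA),
    gene_id = c("g1", "g1", "g2", NA), distance = c(0, 0, 10, NA),
    tied = FALSE)
  co <- build_cohort(asn, "A")
  expect_equal(nrow(co), 2)
  expect_equal(co$magnitude[co$gene_id == "g1"], 2.0)
  expect_equal(co$n_peaks[co$gene_id == "g1"], 2L)
  expect_equal(co$gene_id[co$rank == 1], "g1")

  expect_equal(nrow(build_cohort(asn[is.na(asn$gene_id), ], "A")), 0)
})

test_that("cohort intersection reports sets and fractions symmetrically", {
  a <- build_cohort(tibble::tibble(gene_id = c("g1", "g2", "g3"),
                                   magnitude = c(3, 2, 1)), "A")
  b <- build_cohort(tibble::tibble(gene_id = c("g2", "g3", "g4"),
                                   magnitude = c(5, 4, 3)), "B")
  i <- intersect_cohorts(a, b)
  expect_setequal(i$genes$gene_id, c("g2", "g3"))
  expect_equal(i$summary$overlap_fraction, 2 / 3)
  expect_lte(i$summary$n_common, min(i$summary$n_a, i$summary$n_b))

  i_rev <- intersect_cohorts(b, a)
  expect_setequal(i$genes$gene_id, i_rev$genes$gene_id)

  disjoint <- intersect_cohorts(
    a, build_cohort(tibble::tibble(gene_id = "zz", magnitude = 1), "B"))
  expect_equal(disjoint$summary$n_common, 0)
  expect_equal(disjoint$summary$overlap_fraction, 0)
})

test_that("GFF3 round-trip through 0-based internal coordinates is the identity", {
  g <- make_toy_genome(8, 80000, seed = 4)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_genes(g$genes, path)
  back <- read_genes(path)
  back <- back[match(g$genes$gene_id, back$gene_id), ]
  expect_equal(back$start, g$genes$start)
  expect_equal(back$end, g$genes$end)
  expect_equal(back$strand, g$genes$strand)
})
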