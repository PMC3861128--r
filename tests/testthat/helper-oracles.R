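# Independent oracles used across the suite. Each is deliberately written as
# a plain loop (or exhaustive enumeration), sharing no code with the package
# internals it checks.

# random jittered-grid track
random_track <- function(n, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  st <- as.integer(round(cumsum(runif(n, 44, 66))))
  tibble::tibble(chrom = "chrT", start = st, end = st + 50L,
                 value = rnorm(n, 0, noise_sd))
}

# brute-force run scanner: greedy loop over qualifying probes
bf_scan_peaks <- function(track, threshold, min_probes, max_gap) {
  qual <- which(track$value >= threshold)
  runs <- list()
  cur <- integer(0)
  for (i in qual) {
    if (length(cur) == 0) {
      cur <- i
    } else if (track$start[i] - track$end[cur[length(cur)]] <= max_gap) {
      cur <- c(cur, i)
    } else {
      runs[[length(runs) + 1]] <- cur
      cur <- i
    }
  }
  if (length(cur) > 0) runs[[length(runs) + 1]] <- cur
  runs <- Filter(function(r) length(r) >= min_probes, runs)
  if (length(runs) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          magnitude = numeric(0), n_probes = integer(0)))
  }
  out <- lapply(runs, function(r) {
    tibble::tibble(start = track$start[r[1]], end = track$end[r[length(r)]],
                   magnitude = mean(track$value[r], trim = 0.1),
                   n_probes = length(r))
  })
  do.call(rbind, out)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- sub[r, ]
      rest[rest >= pos] <- rest[rest >= pos] + 1L
      out[row, ] <- c(pos, rest)
      row <- row + 1
    }
  }
  out
}

# exact hypergeometric upper tail by direct enumeration of pmf terms
bf_hyper_tail <- function(k, K, n, N) {
  i <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# brute-force all-pairs peak -> gene assignment
bf_assign <- function(peaks, genes, pad = 500) {
  res <- list()
  for (p in seq_len(nrow(peaks))) {
    ps <- peaks$start[p]; pe <- peaks$end[p]
    best_d <- Inf; cand <- integer(0)
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != peaks$chrom[p]) next
      d <- max(genes$start[g] - pe, ps - genes$end[g], 0)
      if (d > pad) next
      if (d < best_d) { best_d <- d; cand <- g }
      else if (d == best_d) cand <- c(cand, g)
    }
    if (length(cand) == 0) {
      res[[p]] <- tibble::tibble(peak_id = p, gene_id = NA_character_,
                                 distance = NA_real_)
      next
    }
    if (length(cand) > 1) {
      mid <- ps + floor((pe - ps) / 2)
      md <- sapply(cand, function(g)
        max(genes$start[g] - mid, mid - (genes$end[g] - 1), 0))
      cand <- cand[md == min(md)]
    }
    res[[p]] <- tibble::tibble(peak_id = p, gene_id = genes$gene_id[cand],
                               distance = best_d)
  }
  do.call(rbind, res)
}

# naive O(n^3) complete-linkage agglomeration; returns the partition at
# every cluster count k (named list, canonical label form)
bf_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  partitions[[as.character(n)]] <- seq_len(n)
  current <- seq_len(n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merged <- c(clusters[[i]], clusters[[j]])
    clusters <- c(clusters[-c(i, j)], list(merged))
    labels <- integer(n)
    for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci
    partitions[[as.character(length(clusters))]] <- labels
  }
  partitions
}

# canonical form of a partition labeling (order of first appearance)
canon_partition <- function(labels) {
  match(labels, unique(labels))
}

# do two labelings induce the same partition?
same_partition <- function(a, b) {
  identical(canon_partition(a), canon_partition(b))
}
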