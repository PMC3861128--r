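# membership of qualifying probes in gap-limited runs; returns a grouping
# vector parallel to `idx` (indices of qualifying probes)
run_groups <- function(track, idx, max_gap) {
  if (length(idx) == 0) return(integer(0))
  gap <- track$start[idx[-1]] - track$end[idx[-length(idx)]]
  cumsum(c(1L, as.integer(gap > max_gap)))
}

# fast count of peaks (runs with >= min_probes qualifying probes)
count_peaks <- function(value, start, end, threshold, min_probes, max_gap) {
  idx <- which(value >= threshold)
  if (length(idx) < min_probes) return(0L)
  gap <- start[idx[-1]] - end[idx[-length(idx)]]
  grp <- cumsum(c(1L, as.integer(gap > max_gap)))
  sum(tabulate(grp) >= min_probes)
}

#' Scan a track for thresholded probe runs (candidate peaks)
#'
#' A peak is a maximal run of probes with value at or above `threshold`,
#' where consecutive qualifying probes may be separated by at most `max_gap`
#' bp, and the run contains at least `min_probes` qualifying probes. Peak
#' magnitude is the 10% trimmed mean of the member-probe values; the summit
#' (maximum member-probe value) is reported alongside. Peaks are returned
#' sorted by position.
#'
#' @param track A probe track (tibble with `chrom`, `start`, `end`, `value`).
#' @param threshold Calling threshold, log2 units (> 0; gains only by
#'   default -- negate the track to call losses).
#' @param min_probes Minimum qualifying probes per peak (>= 2).
#' @param max_gap Maximum gap (bp) between consecutive qualifying probes.
#'
#' @return A tibble with `chrom`, `start`, `end`, `magnitude`, `summit`,
#'   `n_probes`.
#' @export
#' @examples
#' tr <- tibble::tibble(chrom = "c", start = 0:19 * 55, end = 0:19 * 55 + 50,
#'                      value = c(rep(0, 7), rep(2, 6), rep(0, 7)))
#' scan_peaks(tr, threshold = 1, min_probes = 4)
scan_peaks <- function(track, threshold, min_probes = 4, max_gap = 150) {
  check_track(track)
  min_probes <- check_count(min_probes, "min_probes", min = 2)
  threshold <- check_number(threshold, "threshold", min = 0, strict_min = TRUE)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  magnitude = numeric(), summit = numeric(),
                  n_probes = integer())
  idx <- which(track$value >= threshold)
  if (length(idx) < min_probes) return(empty)
  grp <- run_groups(track, idx, max_gap)
  sizes <- tabulate(grp)
  keep_grp <- which(sizes >= min_probes)
  if (length(keep_grp) == 0) return(empty)
  members <- split(idx, grp)[as.character(keep_grp)]
  map(members, function(m) {
    tibble(chrom = track$chrom[m[1]],
           start = track$start[m[1]],
           end = track$end[m[length(m)]],
           magnitude = mean(track$value[m], trim = 0.1),
           summit = max(track$value[m]),
           n_probes = length(m))
  }) %>% list_rbind() %>% arrange(.data$start)
}

#' Permute probe values across positions (the null model)
#'
#' Uniform whole-track permutation of values with positions fixed: the value
#' multiset is conserved exactly while all spatial structure is destroyed. An
#' optional block permutation (values permuted in blocks of consecutive
#' probes) is available for locally correlated probe noise.
#'
#' @param track A probe track.
#' @param seed Optional integer seed (set for reproducible permutations).
#' @param block Block length in probes; 1 (default) is simple permutation.
#' @return A track with identical positions and permuted values.
#' @export
randomize_track <- function(track, seed = NULL, block = 1) {
  check_track(track)
  block <- check_count(block, "block")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(track)
  if (block == 1) {
    perm <- sample.int(n)
  } else {
    grp <- ceiling(seq_len(n) / block)
    blocks <- split(seq_len(n), grp)
    perm <- unlist(blocks[sample.int(length(blocks))], use.names = FALSE)
  }
  out <- track
  out$value <- track$value[perm]
  attr(out, "kind") <- track_kind(track)
  out
}

#' Permutation-calibrated FDR curve over a threshold grid
#'
#' For each threshold, peaks are counted on the observed track and on
#' `n_permutations` value-permuted null tracks;
#' `fdr(t) = min(1, mean null count / max(1, observed count))`, monotonized to
#' be non-increasing in the threshold by a running minimum from the lenient
#' end (a higher threshold can never be reported as less reliable than a
#' lower one).
#'
#' @inheritParams scan_peaks
#' @param thresholds Increasing threshold grid; default 20 quantile-spaced
#'   levels between the 90th and 99.9th percentile of the track values.
#' @param n_permutations Number of null permutations (>= 1; default 100).
#' @param block Null-model block length in probes (see [randomize_track()]).
#' @param seed Integer seed for the permutations.
#'
#' @return A tibble of class `fdr_curve` with `threshold`, `n_observed`,
#'   `mean_null_count`, `fdr`.
#' @export
estimate_fdr <- function(track, thresholds = NULL, n_permutations = 100,
                         min_probes = 4, max_gap = 150, block = 1, seed = 1) {
  check_track(track)
  n_permutations <- check_count(n_permutations, "n_permutations")
  if (is.null(thresholds)) {
    thresholds <- quantile(track$value, probs = seq(0.90, 0.999, length.out = 20),
                           names = FALSE)
  }
  thresholds <- sort(unique(as.numeric(thresholds)))
  if (length(thresholds) == 0) abort("empty threshold grid.")

  v <- track$value; s <- track$start; e <- track$end
  n_obs <- vapply(thresholds, function(t)
    count_peaks(v, s, e, t, min_probes, max_gap), integer(1))

  set.seed(seed)
  null_counts <- matrix(0L, nrow = n_permutations, ncol = length(thresholds))
  for (p in seq_len(n_permutations)) {
    vp <- randomize_track(track, block = block)$value
    null_counts[p, ] <- vapply(thresholds, function(t)
      count_peaks(vp, s, e, t, min_probes, max_gap), integer(1))
  }
  mean_null <- colMeans(null_counts)
  fdr <- cummin(pmin(1, mean_null / pmax(1, n_obs)))

  out <- tibble(threshold = thresholds, n_observed = n_obs,
                mean_null_count = mean_null, fdr = fdr)
  class(out) <- c("fdr_curve", class(out))
  attr(out, "params") <- list(n_permutations = n_permutations,
                              min_probes = min_probes, max_gap = max_gap,
                              block = block, seed = seed)
  out
}

#' Call peaks at the FDR-selected threshold and apply the enrichment filter
#'
#' Chooses the least stringent threshold on the FDR curve with
#' `fdr < fdr_cutoff`, scans the track there, and retains peaks whose
#' enrichment score exceeds `enrichment_cutoff`. The enrichment score is the
#' peak *summit* (its maximum member-probe value) rescaled between the track
#' median (score 0) and the track maximum (score 1): summit and track maximum
#' are order statistics of the same probe-level distribution, so the score is
#' self-calibrating across noise levels, and a peak culminating at the track
#' maximum scores exactly 1. Each retained peak is annotated with the curve's
#' FDR at the used threshold. If no threshold passes, an empty peak set is
#' returned with the reason recorded in `attr(, "reason")`.
#'
#' @inheritParams scan_peaks
#' @param fdr_curve An [estimate_fdr()] result for the same track.
#' @param fdr_cutoff FDR ceiling (default 0.05).
#' @param enrichment_cutoff Minimum enrichment score (default 0.5).
#'
#' @return A tibble of class `peak_set` with `chrom`, `start`, `end`,
#'   `magnitude`, `summit`, `n_probes`, `enrichment_score`, `fdr`; the used
#'   threshold in `attr(, "threshold")`.
#' @export
select_peaks <- function(track, fdr_curve, fdr_cutoff = 0.05,
                         enrichment_cutoff = 0.5, min_probes = 4,
                         max_gap = 150) {
  check_track(track)
  stopifnot(inherits(fdr_curve, "fdr_curve"))
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  magnitude = numeric(), summit = numeric(),
                  n_probes = integer(),
                  enrichment_score = numeric(), fdr = numeric())
  class(empty) <- c("peak_set", class(empty))

  ok <- fdr_curve$fdr < fdr_cutoff
  if (!any(ok)) {
    attr(empty, "reason") <- sprintf(
      "no threshold reached FDR < %g (minimum achieved: %g)",
      fdr_cutoff, min(fdr_curve$fdr))
    return(empty)
  }
  thr <- min(fdr_curve$threshold[ok])
  peaks <- scan_peaks(track, thr, min_probes = min_probes, max_gap = max_gap)
  med <- median(track$value)
  mx <- max(track$value)
  if (nrow(peaks) == 0) {
    attr(empty, "reason") <- "no peaks at the selected threshold"
    attr(empty, "threshold") <- thr
    return(empty)
  }
  peaks <- peaks %>%
    mutate(enrichment_score = (.data$summit - med) / (mx - med),
           fdr = fdr_curve$fdr[match(thr, fdr_curve$threshold)]) %>%
    filter(.data$enrichment_score > enrichment_cutoff)
  class(peaks) <- c("peak_set", class(peaks))
  attr(peaks, "threshold") <- thr
  attr(peaks, "track_median") <- med
  attr(peaks, "track_max") <- mx
  peaks
}
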