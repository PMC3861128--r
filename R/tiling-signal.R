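# generalized-log (arsinh-type) transform; equals log2(x) when c = 0
glog2 <- function(x, c) log2((x + sqrt(x^2 + c^2)) / 2)

#' Variance-stabilized log ratio of two probe channels
#'
#' Turns raw IP and input intensities into a per-probe log2-ratio track using
#' a generalized-log (arsinh-type) transform with a robust per-channel scale:
#' `value = glog2(ip) - glog2(input)` where each channel's glog scale is its
#' MAD. At high intensity the glog converges to `log2`, so a constant
#' intensity ratio of 2 gives a value of 1. With `calibrate = TRUE` (default)
#' the channels are additionally calibrated to each other by robust median
#' matching on the glog scale, i.e. the output track has median 0; disable it
#' to read off absolute channel ratios.
#'
#' Probes where both channels are zero (masked spots) are dropped, never
#' imputed: interpolation would fabricate evidence inside peaks.
#'
#' @param probes A data frame with columns `chrom`, `start`, `end` and the two
#'   intensity columns.
#' @param ip,input Names of the IP and input intensity columns.
#' @param calibrate Robustly calibrate the channels to each other (median
#'   matching; output median 0)?
#'
#' @return A probe track tibble (`chrom`, `start`, `end`, `value`) of kind
#'   `ip_over_input`, with the calibration parameters in `attr(, "params")`.
#' @export
#' @examples
#' probes <- data.frame(chrom = "c", start = 0:9 * 55, end = 0:9 * 55 + 50,
#'                      ip = 2^(10 + rnorm(10, 0, .1)), input = 2^10)
#' stabilize_and_log(probes)
stabilize_and_log <- function(probes, ip = "ip", input = "input",
                              calibrate = TRUE) {
  stopifnot(is.data.frame(probes),
            all(c("chrom", "start", "end", ip, input) %in% names(probes)))
  a <- as.numeric(probes[[ip]])
  b <- as.numeric(probes[[input]])
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative.")
  }
  keep <- is.finite(a) & is.finite(b) & !(a == 0 & b == 0)
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0 || all(a == 0) || all(b == 0)) {
    abort("degenerate input: a channel is all zero.")
  }

  glog_scale <- function(x) {
    s <- mad(x)
    if (s == 0) s <- sd(x)
    if (is.na(s) || s == 0) {
      s <- if (any(x == 0)) min(x[x > 0]) / 2 else 0
    }
    s
  }
  c_a <- glog_scale(a)
  c_b <- glog_scale(b)
  value <- glog2(a, c_a) - glog2(b, c_b)
  offset <- 0
  if (calibrate) {
    offset <- median(value)
    value <- value - offset
  }
  grid <- probes[keep, c("chrom", "start", "end")]
  new_track(grid, value, kind = "ip_over_input",
            params = list(glog_scale_ip = c_a, glog_scale_input = c_b,
                          calibration_offset = offset,
                          n_dropped = sum(!keep)))
}

#' Drug-vs-control difference track
#'
#' Per-probe difference of two log2-ratio tracks on an identical probe grid;
#' positive values mark drug-induced acetylation gains. Mismatched grids
#' signal an upstream bug and are an error -- there is no silent intersection.
#'
#' @param ip_drug,ip_control Probe tracks on the same grid.
#' @return A track of kind `drug_over_control`.
#' @export
difference_track <- function(ip_drug, ip_control) {
  check_track(ip_drug, "ip_drug")
  check_track(ip_control, "ip_control")
  if (!same_grid(ip_drug, ip_control)) {
    abort("tracks are not on the same probe grid; refusing to intersect silently.")
  }
  new_track(ip_drug[, c("chrom", "start", "end")],
            ip_drug$value - ip_control$value,
            kind = "drug_over_control")
}

#' Probewise average of replicate tracks
#'
#' @param tracks A non-empty list of tracks on a common probe grid.
#' @return A track of the same kind with the probewise mean value; the
#'   replicate count is recorded in `attr(, "params")`.
#' @export
average_replicates <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0 || is.data.frame(tracks)) {
    abort("`tracks` must be a non-empty list of tracks.")
  }
  purrr::walk(tracks, check_track)
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!same_grid(ref, t)) abort("replicate tracks must share one probe grid.")
  }
  value <- Reduce(`+`, map(tracks, "value")) / length(tracks)
  new_track(ref[, c("chrom", "start", "end")], value,
            kind = track_kind(ref),
            params = list(n_replicates = length(tracks)))
}

#' Median-center a set of tracks to a common level
#'
#' Between-array normalization: each track is shifted so its median equals the
#' grand median of all supplied track values. Within-track probe ordering is
#' unchanged.
#'
#' @param tracks A list of >= 2 tracks.
#' @return A list of shifted tracks, all with the same median.
#' @export
median_center <- function(tracks) {
  if (!is.list(tracks) || length(tracks) < 2 || is.data.frame(tracks)) {
    abort("`tracks` must be a list of at least two tracks.")
  }
  purrr::walk(tracks, check_track)
  grand <- median(unlist(map(tracks, "value")))
  map(tracks, function(t) {
    shifted <- t
    shifted$value <- t$value - median(t$value) + grand
    attr(shifted, "kind") <- track_kind(t)
    shifted
  })
}

#' Array-normality QC report
#'
#' The pipeline's QC rule is a *flag*, not an automatic filter: silent sample
#' dropping is hostile to reproducibility. Each track's log-scale values get
#' an Anderson-Darling normality statistic; tracks with p below `alpha` are
#' flagged for manual review.
#'
#' @param tracks A track or list of tracks.
#' @param alpha Flagging threshold on the normality p-value.
#' @return A tibble with `track`, `n`, `statistic`, `p_value`, `flagged`.
#' @export
track_normality_qc <- function(tracks, alpha = 0.01) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  purrr::walk(tracks, check_track)
  nm <- names(tracks) %||% paste0("track_", seq_along(tracks))
  if (is.null(names(tracks))) names(tracks) <- nm
  imap(tracks, function(t, id) {
    ad <- nortest::ad.test(t$value)
    tibble(track = id, n = nrow(t),
           statistic = unname(ad$statistic), p_value = ad$p.value,
           flagged = ad$p.value < alpha)
  }) %>% list_rbind()
}

#' Replicate-averaged drug-vs-control difference track from a simulation
#'
#' Convenience composition of the signal stages on a simulated experiment:
#' each condition/replicate channel pair is stabilized to an IP/input track,
#' replicate-matched drug-minus-control differences are formed, and the
#' replicate difference tracks are averaged.
#'
#' @param sim A [simulate_tiling_experiment()] result.
#' @param drug `"A"` or `"B"`.
#' @return A `drug_over_control` track.
#' @export
difference_from_sim <- function(sim, drug = c("A", "B")) {
  drug <- match.arg(drug)
  cond <- paste0("drug", drug)
  diffs <- map(seq_len(sim$n_replicates), function(r) {
    difference_track(
      stabilize_and_log(sim_channel(sim, cond, r)),
      stabilize_and_log(sim_channel(sim, "control", r))
    )
  })
  average_replicates(diffs)
}
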