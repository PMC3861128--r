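#' Simulate sedation-recovery datasets from Richards-distributed fly times
#'
#' For every line and group (naive control vs drug pre-exposed), each fly's
#' recovery time is drawn by inverse-transform sampling from the Richards
#' curve implied by the group's true 50%-recovery time and the shared shape
#' parameters, so the downstream curve-fitting stage is internally consistent
#' with the generator and parameter recovery is a sharp test. Recoveries are
#' then tallied per vial at the observation interval, giving monotone
#' non-decreasing cumulative percentages.
#'
#' @param lines A data frame with columns `line`, `t50_control`,
#'   `t50_exposed` (true 50%-recovery times in minutes for the naive and
#'   pre-exposed groups).
#' @param n_vials Vials per group (default 3).
#' @param flies_per_vial Flies per vial (default 12).
#' @param interval Observation interval in minutes (default 5, the
#'   benzyl-alcohol scoring interval; ethanol assays use 2).
#' @param A,K Lower/upper asymptote of the population curve in percent
#'   (0 <= A < K <= 100; flies beyond `K`% never recover and stay censored).
#' @param B Rate parameter (per minute).
#' @param nu Asymmetry parameter (> 0; 1 gives a symmetric logistic).
#' @param t_max Last observation time; defaults to a small multiple of the
#'   largest true t50, rounded up to the interval.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `line`, `group` (`control`/`pre_exposed`),
#'   `vial`, `time_min`, `n_recovered` (cumulative), `n_total`.
#' @export
#' @examples
#' rec <- simulate_recovery_dataset(
#'   data.frame(line = "wt", t50_control = 60, t50_exposed = 40), seed = 1)
#' head(rec)
simulate_recovery_dataset <- function(lines, n_vials = 3, flies_per_vial = 12,
                                      interval = 5, A = 0, K = 100, B = 0.2,
                                      nu = 1, t_max = NULL, seed = 1) {
  stopifnot(is.data.frame(lines),
            all(c("line", "t50_control", "t50_exposed") %in% names(lines)))
  if (any(c(lines$t50_control, lines$t50_exposed) <= 0)) {
    abort("true t50 values must be positive.")
  }
  interval <- check_number(interval, "interval", min = 0, strict_min = TRUE)
  if (!(A >= 0 && A < K && K <= 100)) abort("need 0 <= A < K <= 100.")
  if (B <= 0 || nu <= 0) abort("`B` and `nu` must be positive.")
  set.seed(seed)

  # offset between t50 and the inflection-location parameter M
  m_from_t50 <- function(t50) t50 + log(((K - A) / (50 - A))^nu - 1) / B
  if (!(A < 50 && K > 50)) {
    abort("the population curve must cross 50% (A < 50 < K).")
  }

  if (is.null(t_max)) {
    t_max <- interval * ceiling(2.5 * max(lines$t50_control, lines$t50_exposed) / interval)
  }
  times <- seq(interval, t_max, by = interval)

  rows <- list()
  for (i in seq_len(nrow(lines))) {
    for (grp in c("control", "pre_exposed")) {
      t50 <- if (grp == "control") lines$t50_control[i] else lines$t50_exposed[i]
      M <- m_from_t50(t50)
      for (v in seq_len(n_vials)) {
        u <- runif(flies_per_vial)
        # P(recovered by t) = (A + (K - A) * (1 + exp(-B (t - M)))^(-1/nu)) / 100
        frac <- (100 * u - A) / (K - A)
        t_fly <- rep(Inf, flies_per_vial)
        t_fly[u < A / 100] <- 0
        ok <- frac > 0 & frac < 1
        t_fly[ok] <- M - log(frac[ok]^(-nu) - 1) / B
        counts <- vapply(times, function(tt) sum(t_fly <= tt), integer(1))
        rows[[paste(i, grp, v)]] <- tibble(
          line = lines$line[i], group = grp, vial = v, time_min = times,
          n_recovered = counts, n_total = flies_per_vial
        )
      }
    }
  }
  bind_rows(rows)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Draws target and reference Ct values such that the delta-delta-Ct estimate
#' `2^-ddCt` recovers each gene's specified treated-vs-control fold change in
#' expectation, under the method's perfect-doubling efficiency assumption.
#'
#' @param effects A data frame with columns `gene` and `fold` (> 0), the true
#'   treated/control expression fold change per gene.
#' @param ct_ref_mean Mean reference-gene Ct (cycles).
#' @param ct_target_mean Mean target Ct in the control condition (cycles).
#' @param noise_sd Per-reaction Ct noise sd (cycles; 0 gives exact values).
#' @param n_replicates Replicate reactions per gene and condition (default 8).
#' @param treated,control Condition labels.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `sample`, `condition`, `gene`, `ct_target`,
#'   `ct_reference`.
#' @export
simulate_qpcr <- function(effects, ct_ref_mean = 16, ct_target_mean = 22,
                          noise_sd = 0.2, n_replicates = 8,
                          treated = "treated", control = "control", seed = 1) {
  stopifnot(is.data.frame(effects), all(c("gene", "fold") %in% names(effects)))
  if (any(effects$fold <= 0)) abort("fold changes must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  n_replicates <- check_count(n_replicates, "n_replicates")
  set.seed(seed)

  rows <- list()
  for (i in seq_len(nrow(effects))) {
    for (cond in c(control, treated)) {
      mu_t <- ct_target_mean - if (cond == treated) log2(effects$fold[i]) else 0
      rows[[paste(i, cond)]] <- tibble(
        sample = sprintf("%s_%s_r%02d", effects$gene[i], cond, seq_len(n_replicates)),
        condition = cond, gene = effects$gene[i],
        ct_target = mu_t + rnorm(n_replicates, 0, noise_sd),
        ct_reference = ct_ref_mean + rnorm(n_replicates, 0, noise_sd)
      )
    }
  }
  bind_rows(rows)
}
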