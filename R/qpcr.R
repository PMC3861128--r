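#' Delta-delta-Ct relative expression with Dunnett comparisons
#'
#' Per sample, `dCt = Ct_target - Ct_reference` (expression relative to the
#' reference gene); per gene and treated condition,
#' `ddCt = mean dCt(treated) - mean dCt(control)` and the fold change is
#' `2^-ddCt`, under the method's perfect-doubling efficiency assumption. The
#' SE is propagated from the replicate dCt variances, and per-gene
#' significance against the control condition uses a one-way ANOVA on dCt
#' with Dunnett many-to-one comparisons (two-sided).
#'
#' @param records A data frame with columns `sample`, `condition`, `gene`,
#'   `ct_target`, `ct_reference`.
#' @param control Label of the control condition (default `"control"`).
#' @return A tibble with one row per gene and non-control condition: `gene`,
#'   `condition`, `n_treated`, `n_control`, `ddct`, `fold`, `fold_se`,
#'   `p_value` (NA when replicates do not allow a test).
#' @export
#' @examples
#' ct <- simulate_qpcr(data.frame(gene = "eag", fold = 2), noise_sd = 0)
#' delta_delta_ct(ct)
delta_delta_ct <- function(records, control = "control") {
  stopifnot(is.data.frame(records),
            all(c("condition", "gene", "ct_target", "ct_reference") %in% names(records)))
  if (any(!is.finite(records$ct_target)) || any(!is.finite(records$ct_reference)) ||
      any(records$ct_target <= 0) || any(records$ct_reference <= 0)) {
    abort("Ct values must be finite and positive.")
  }
  if (!control %in% records$condition) abort("missing control condition.")
  records <- records %>% mutate(dct = .data$ct_target - .data$ct_reference)

  res <- map(unique(records$gene), function(g) {
    dat <- records %>% filter(.data$gene == g)
    ctl <- dat %>% filter(.data$condition == control)
    if (nrow(ctl) == 0) abort(paste0("gene ", g, ": no control replicates."))
    treated_levels <- setdiff(unique(dat$condition), control)
    if (length(treated_levels) == 0) return(NULL)

    p_values <- setNames(rep(NA_real_, length(treated_levels)), treated_levels)
    counts <- table(dat$condition)
    if (all(counts >= 2)) {
      dat$condition <- factor(dat$condition, levels = c(control, treated_levels))
      fit <- aov(dct ~ condition, data = dat)
      # an essentially perfect fit (zero residual variance) has no usable test
      dn <- tryCatch(
        suppressWarnings(summary(
          multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett")))),
        error = function(e) NULL)
      if (!is.null(dn)) {
        nm <- sub(" - .*$", "", names(dn$test$coefficients))
        p_values[nm] <- as.numeric(dn$test$pvalues)
      }
    }

    map(treated_levels, function(cond) {
      trt <- dat %>% filter(.data$condition == cond)
      ddct <- mean(trt$dct) - mean(ctl$dct)
      se_ddct <- sqrt(var(trt$dct) / nrow(trt) + var(ctl$dct) / nrow(ctl))
      if (nrow(trt) < 2 || nrow(ctl) < 2) se_ddct <- NA_real_
      fold <- 2^(-ddct)
      tibble(gene = g, condition = cond,
             n_treated = nrow(trt), n_control = nrow(ctl),
             ddct = ddct, fold = fold,
             fold_se = log(2) * fold * se_ddct,
             p_value = unname(p_values[cond]))
    }) %>% list_rbind()
  }) %>% list_rbind()
  res
}

#' Mean array signal over the probes nearest a locus center
#'
#' Averages the track values of the `n_probes` probes whose midpoints lie
#' nearest to `center` (ties resolved toward the lower coordinate), the
#' window statistic used to compare tiling-array signal with ChIP-qPCR at
#' primer loci. A center beyond the probe grid simply takes the closest
#' `n_probes` probes (e.g. the last seven).
#'
#' @param track A probe track.
#' @param center Locus center in bp.
#' @param n_probes Window size in probes (default 7).
#' @return A one-row tibble: `center`, `n_probes`, `window_start`,
#'   `window_end`, `mean`, `sem`; the member probes in `attr(, "probes")`.
#' @export
window_mean_signal <- function(track, center, n_probes = 7) {
  check_track(track)
  n_probes <- check_count(n_probes, "n_probes")
  if (nrow(track) < n_probes) {
    abort("track has fewer probes than the requested window.")
  }
  mid <- (track$start + track$end) / 2
  ord <- order(abs(mid - center), mid)
  idx <- sort(ord[seq_len(n_probes)])
  vals <- track$value[idx]
  out <- tibble(center = center, n_probes = n_probes,
                window_start = track$start[idx[1]],
                window_end = track$end[idx[n_probes]],
                mean = mean(vals), sem = sd(vals) / sqrt(n_probes))
  attr(out, "probes") <- track[idx, ]
  out
}

#' Pearson correlation between qPCR and array signal across loci
#'
#' @param pairs A data frame of per-locus signal pairs.
#' @param qpcr,array Names of the qPCR-ratio and array-signal columns.
#' @return A one-row tibble: `r`, `p_value`, `n`, `conf_low`, `conf_high`
#'   (two-sided test via the t transform).
#' @export
crossplatform_correlation <- function(pairs, qpcr = "qpcr_ratio",
                                      array = "array_signal") {
  stopifnot(is.data.frame(pairs), all(c(qpcr, array) %in% names(pairs)))
  x <- pairs[[qpcr]]; y <- pairs[[array]]
  if (length(x) < 3) abort("need at least 3 loci.")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance signal column.")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         conf_low = ct$conf.int[1], conf_high = ct$conf.int[2])
}
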