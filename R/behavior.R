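#' Five-parameter Richards curve
#'
#' `Y(t) = A + (K - A) / (1 + exp(-B (t - M)))^(1/nu)`: an asymmetric sigmoid
#' with lower/upper asymptotes `A`/`K` (percent recovered), rate `B` (per
#' minute), location `M` (minutes) and asymmetry `nu` (> 0; `nu = 1` is the
#' symmetric logistic, where `Y(M) = (A + K)/2`).
#'
#' @param t Time(s) in minutes.
#' @param A,K,B,M,nu Curve parameters.
#' @return Percent recovered at `t`.
#' @export
richards_curve <- function(t, A, K, B, M, nu) {
  A + (K - A) / (1 + exp(-B * (t - M)))^(1 / nu)
}

#' Time at which a Richards curve crosses absolute 50% recovery
#'
#' `t50` is defined on the absolute scale -- the time at which the fitted
#' curve crosses 50% of the population recovered -- not the half-way point
#' between the asymptotes, because recovery assays score populations out of
#' 100% and their curves saturate near 100%. Closed form by inverting the
#' Richards expression; `NA` (undefined) when the curve never crosses 50
#' (`A >= 50` or `K <= 50`).
#'
#' @inheritParams richards_curve
#' @return `t50` in minutes, or `NA_real_` when undefined.
#' @export
richards_t50 <- function(A, K, B, M, nu) {
  if (!(A < 50 && K > 50) || B <= 0 || nu <= 0) return(NA_real_)
  q <- ((K - A) / (50 - A))^nu - 1
  M - log(q) / B
}

# bisection fallback/cross-check for the closed-form inversion
richards_t50_bisect <- function(A, K, B, M, nu, lower = M - 2000, upper = M + 2000,
                                tol = 1e-12) {
  if (!(A < 50 && K > 50)) return(NA_real_)
  f <- function(t) richards_curve(t, A, K, B, M, nu) - 50
  while (f(lower) > 0) lower <- lower - 2000
  while (f(upper) < 0) upper <- upper + 2000
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

# percent-recovered column from counts if not supplied directly
recovery_percent <- function(curves) {
  if ("percent" %in% names(curves)) return(curves$percent)
  if (all(c("n_recovered", "n_total") %in% names(curves))) {
    return(100 * curves$n_recovered / curves$n_total)
  }
  abort("curves need a `percent` column or `n_recovered` + `n_total`.")
}

richards_start_grid <- function(t, y) {
  K0 <- max(y)
  ymax <- max(y)
  t_at <- function(frac) {
    target <- frac * ymax
    t[which.min(abs(y - target))]
  }
  starts <- expand.grid(M = unique(c(t_at(0.4), t_at(0.6))),
                        B = c(0.1, 0.3), nu = c(0.7, 2))
  purrr::pmap(starts, function(M, B, nu) {
    list(A = 0, K = max(K0, 20), B = B, M = M, nu = nu)
  })
}

#' Fit a five-parameter Richards recovery curve
#'
#' Least-squares fit of the Richards curve to percent-recovered observations,
#' pooled over vials, by Levenberg-Marquardt with a coarse multi-start grid
#' over (M, B, nu) -- five-parameter sigmoids are multi-modal, so the best
#' converged start by SSE wins. `t50` is solved in closed form from the
#' fitted parameters (with a bisection cross-check available via
#' [richards_t50()]); parameter standard errors come from the Jacobian at
#' the optimum, and the t50 SE by the delta method. When the data carry a
#' `vial` column with >= 3 vials, per-vial fits (started from the pooled
#' optimum) give a vial-level t50 SEM as well.
#'
#' @param curves A data frame with `time_min` plus either `percent` or
#'   `n_recovered`/`n_total`, optionally `vial`.
#' @param fit_vials Also fit each vial separately (default TRUE when a vial
#'   column is present)?
#' @return An object of class `richards_fit` with elements `coefficients`
#'   (A, K, B, M, nu), `se`, `vcov`, `t50`, `t50_se`, `t50_defined`,
#'   `vial_t50` (tibble or NULL), `t50_vial_sem`, `sse`, `n_obs`,
#'   `interval` (median observation spacing).
#' @export
#' @examples
#' t <- seq(5, 80, by = 5)
#' d <- data.frame(time_min = t, percent = richards_curve(t, 0, 100, .2, 30, 1))
#' fit_richards(d)$t50
fit_richards <- function(curves, fit_vials = TRUE) {
  stopifnot(is.data.frame(curves), "time_min" %in% names(curves))
  y <- recovery_percent(curves)
  t <- curves$time_min
  if (length(unique(t)) < 4) abort("need >= 4 distinct time points.")
  if (sd(y) == 0) {
    abort("degenerate recovery data: no spread (50% recovery never observed).")
  }

  fit_one <- function(tt, yy, starts) {
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          yy ~ richards_curve(tt, A, K, B, M, nu),
          start = st,
          lower = c(A = 0, K = 10, B = 1e-4, M = 0, nu = 0.05),
          upper = c(A = 45, K = 110, B = 5, M = max(tt) * 3, nu = 20),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
    best
  }

  best <- fit_one(t, y, richards_start_grid(t, y))
  if (is.null(best)) {
    abort("Richards fit did not converge from any start; inspect the curves.")
  }
  cf <- coef(best$fit)
  V <- tryCatch(vcov(best$fit), error = function(e) matrix(NA_real_, 5, 5))
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(cf)

  t50 <- richards_t50(cf["A"], cf["K"], cf["B"], cf["M"], cf["nu"])
  t50_defined <- is.finite(t50)
  t50_se <- NA_real_
  if (t50_defined && all(is.finite(V))) {
    # delta method with a numeric gradient of t50 in the parameters
    eps <- pmax(abs(cf) * 1e-5, 1e-7)
    grad <- vapply(seq_along(cf), function(j) {
      up <- cf; up[j] <- up[j] + eps[j]
      dn <- cf; dn[j] <- dn[j] - eps[j]
      (richards_t50(up["A"], up["K"], up["B"], up["M"], up["nu"]) -
         richards_t50(dn["A"], dn["K"], dn["B"], dn["M"], dn["nu"])) / (2 * eps[j])
    }, numeric(1))
    if (all(is.finite(grad))) {
      t50_se <- sqrt(max(drop(t(grad) %*% V %*% grad), 0))
    }
  }

  vial_t50 <- NULL
  t50_vial_sem <- NA_real_
  if (fit_vials && "vial" %in% names(curves) &&
      length(unique(curves$vial)) >= 3) {
    pooled_start <- list(as.list(cf))
    vial_t50 <- map(split(seq_len(nrow(curves)), curves$vial), function(ix) {
      vb <- fit_one(t[ix], y[ix], pooled_start)
      if (is.null(vb)) return(NA_real_)
      vcf <- coef(vb$fit)
      richards_t50(vcf["A"], vcf["K"], vcf["B"], vcf["M"], vcf["nu"])
    })
    vial_t50 <- tibble(vial = names(vial_t50),
                       t50 = unname(unlist(vial_t50)))
    ok <- is.finite(vial_t50$t50)
    if (sum(ok) >= 2) {
      t50_vial_sem <- sd(vial_t50$t50[ok]) / sqrt(sum(ok))
    }
  }

  structure(
    list(coefficients = cf, se = se, vcov = V, t50 = unname(t50),
         t50_se = unname(t50_se), t50_defined = t50_defined,
         vial_t50 = vial_t50, t50_vial_sem = t50_vial_sem,
         sse = best$sse, n_obs = length(y),
         interval = median(diff(sort(unique(t)))),
         data = tibble(time_min = t, percent = y)),
    class = "richards_fit"
  )
}

#' @export
print.richards_fit <- function(x, ...) {
  cat("<richards_fit> t50 = ",
      if (x$t50_defined) sprintf("%.2f min (SE %.2f)", x$t50, x$t50_se)
      else "undefined (curve never crosses 50%)",
      "; SSE = ", sprintf("%.1f", x$sse), " over ", x$n_obs, " points\n", sep = "")
  invisible(x)
}

#' @export
tidy.richards_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se))
}

#' @export
glance.richards_fit <- function(x, ...) {
  tibble(t50 = x$t50, t50_se = x$t50_se, t50_vial_sem = x$t50_vial_sem,
         sse = x$sse, n_obs = x$n_obs,
         n_vials = if (is.null(x$vial_t50)) NA_integer_ else nrow(x$vial_t50))
}

#' Tolerance magnitude between naive and pre-exposed fits
#'
#' `delta_t50 = t50(control) - t50(pre-exposed)`: positive when the
#' pre-exposed group recovered faster, i.e. acquired tolerance. The SE
#' combines the two groups' t50 SEs in quadrature, preferring the vial-level
#' SEMs when both fits carry them: the delta-method SE of a pooled
#' least-squares fit assumes independent residuals, but cumulative recovery
#' counts are strongly autocorrelated within a vial, so the between-vial
#' spread is the honest uncertainty for a group's t50. An undefined t50 in
#' either fit propagates as a flagged missing result rather than an error.
#'
#' @param control_fit,exposed_fit [fit_richards()] results for the two groups.
#' @return A one-row tibble: `delta_t50`, `se`, `t50_control`,
#'   `t50_exposed`, `defined`.
#' @export
tolerance_magnitude <- function(control_fit, exposed_fit) {
  stopifnot(inherits(control_fit, "richards_fit"),
            inherits(exposed_fit, "richards_fit"))
  defined <- control_fit$t50_defined && exposed_fit$t50_defined
  se_of <- function(f) {
    if (is.finite(f$t50_vial_sem)) f$t50_vial_sem else f$t50_se
  }
  tibble(
    delta_t50 = if (defined) control_fit$t50 - exposed_fit$t50 else NA_real_,
    se = if (defined) sqrt(se_of(control_fit)^2 + se_of(exposed_fit)^2) else NA_real_,
    t50_control = control_fit$t50,
    t50_exposed = exposed_fit$t50,
    defined = defined
  )
}

#' Compare tolerance magnitudes across lines against a reference line
#'
#' Runs the full behavioral pipeline on a recovery dataset: per line and
#' group, a pooled Richards fit plus per-vial fits; per-vial tolerance
#' magnitudes (control vial j's t50 minus pre-exposed vial j's t50 -- vials
#' of the two groups are assayed in tandem, and pairing keeps the per-vial
#' magnitudes independent of each other) enter a one-way ANOVA across lines,
#' followed by Dunnett many-to-one comparisons against the reference line
#' (one-sided: a line is called `reduced` when its magnitude is significantly
#' lower than the reference's at `alpha`, otherwise `unchanged`).
#'
#' @param recovery A tibble as produced by [simulate_recovery_dataset()]
#'   (columns `line`, `group`, `vial`, `time_min`, `n_recovered`, `n_total`
#'   or `percent`); `group` must contain `control` and one other level.
#' @param reference Reference (wild-type) line id.
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `tolerance_comparison`: one row per line with
#'   `line`, `delta_t50` (pooled-fit magnitude), `se`, `magnitude_vials`
#'   (mean of per-vial magnitudes), `n_vials`, `p_value`, `verdict`
#'   (`reference`/`reduced`/`unchanged`).
#' @export
compare_lines <- function(recovery, reference, alpha = 0.05) {
  stopifnot(is.data.frame(recovery),
            all(c("line", "group", "vial", "time_min") %in% names(recovery)))
  groups <- unique(recovery$group)
  if (!("control" %in% groups) || length(groups) != 2) {
    abort("`group` must have exactly two levels, one of them \"control\".")
  }
  exposed_label <- setdiff(groups, "control")
  lines <- unique(recovery$line)
  if (!reference %in% lines) abort("reference line not present in the data.")

  per_line <- map(lines, function(l) {
    dat <- recovery %>% filter(.data$line == l)
    ctl <- fit_richards(dat %>% filter(.data$group == "control"))
    exp_ <- fit_richards(dat %>% filter(.data$group == exposed_label))
    mag <- tolerance_magnitude(ctl, exp_)
    ctl_vials <- ctl$vial_t50
    exp_vials <- exp_$vial_t50
    if (is.null(ctl_vials) || is.null(exp_vials)) {
      abort("need >= 3 vials per group for vial-level variance estimation.")
    }
    paired <- inner_join(rename(ctl_vials, t50_control = "t50"),
                         rename(exp_vials, t50_exposed = "t50"),
                         by = "vial")
    paired <- paired[is.finite(paired$t50_control) &
                       is.finite(paired$t50_exposed), ]
    vial_mags <- tibble(line = l,
                        magnitude = paired$t50_control - paired$t50_exposed)
    if (nrow(vial_mags) < 2) {
      abort(paste0("line ", l, ": fewer than 2 usable vial pairs."))
    }
    list(summary = mag %>% mutate(line = l), vials = vial_mags)
  })
  vial_df <- map(per_line, "vials") %>% list_rbind() %>%
    mutate(line = factor(.data$line, levels = c(reference, setdiff(lines, reference))))

  p_values <- setNames(rep(NA_real_, length(lines)), lines)
  if (length(lines) > 1) {
    fit <- aov(magnitude ~ line, data = vial_df)
    dn <- multcomp::glht(fit, linfct = multcomp::mcp(line = "Dunnett"),
                         alternative = "less")
    sm <- summary(dn)
    test_lines <- sub(" - .*$", "", names(sm$test$coefficients))
    p_values[test_lines] <- as.numeric(sm$test$pvalues)
  }

  out <- map(seq_along(lines), function(i) {
    l <- lines[i]
    s <- per_line[[i]]$summary
    tibble(
      line = l,
      delta_t50 = s$delta_t50, se = s$se,
      magnitude_vials = mean(per_line[[i]]$vials$magnitude),
      n_vials = nrow(per_line[[i]]$vials),
      p_value = unname(p_values[l]),
      verdict = if (l == reference) "reference"
                else if (!is.na(p_values[l]) && p_values[l] < alpha) "reduced"
                else "unchanged"
    )
  }) %>% list_rbind()
  class(out) <- c("tolerance_comparison", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "reference") <- reference
  out
}

# accepted effect-call symbols (ASCII and typographic minus)
normalize_call <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("-", "−")] <- "-"
  bad <- !x %in% c("+", "-", "L")
  if (any(bad)) {
    abort(paste0("unknown effect-call symbol(s): ",
                 paste(unique(x[bad]), collapse = ", "),
                 " (expected +, -, or L)."))
  }
  x
}

#' Tally per-line tolerance effect calls across two drugs
#'
#' Summarizes a table of per-line behavioral calls (`+` tolerance
#' significantly blocked or reduced, `-` no effect, `L` lethal and untestable)
#' for two drugs: positives per drug, lines positive for both drugs, and the
#' per-cluster both-drug validation fraction. Lethal lines are excluded from
#' all denominators.
#'
#' @param effect_table A data frame with columns `gene`, `cluster`, and the
#'   two call columns `etoh`, `ba`.
#' @return An object of class `tolerance_tally`: `$totals` (per-drug counts),
#'   `$n_both_positive`, `$by_cluster` (tibble with `cluster`, `n_rows`,
#'   `n_tested`, `n_both_positive`, `validation_percent`).
#' @export
#' @examples
#' tally_effects(read_effect_calls())$totals
tally_effects <- function(effect_table) {
  stopifnot(is.data.frame(effect_table),
            all(c("gene", "cluster", "etoh", "ba") %in% names(effect_table)))
  et <- normalize_call(effect_table$etoh)
  ba <- normalize_call(effect_table$ba)

  totals <- tibble(
    drug = c("ethanol", "benzyl_alcohol"),
    n_positive = c(sum(et == "+"), sum(ba == "+")),
    n_negative = c(sum(et == "-"), sum(ba == "-")),
    n_lethal = c(sum(et == "L"), sum(ba == "L")),
    n_rows = nrow(effect_table)
  )
  tested <- et != "L" & ba != "L"
  both <- tested & et == "+" & ba == "+"
  by_cluster <- tibble(cluster = effect_table$cluster, tested = tested,
                       both = both) %>%
    group_by(.data$cluster) %>%
    summarise(n_rows = n(), n_tested = sum(.data$tested),
              n_both_positive = sum(.data$both),
              validation_percent =
                ifelse(sum(.data$tested) > 0,
                       100 * sum(.data$both) / sum(.data$tested), NA_real_),
              .groups = "drop")
  structure(list(totals = totals, n_both_positive = sum(both),
                 by_cluster = by_cluster),
            class = "tolerance_tally")
}

#' @export
print.tolerance_tally <- function(x, ...) {
  cat("<tolerance_tally> positives: ",
      paste(sprintf("%s %d/%d", x$totals$drug,
                    x$totals$n_positive,
                    x$totals$n_rows - x$totals$n_lethal), collapse = ", "),
      "; both drugs: ", x$n_both_positive, "\n", sep = "")
  invisible(x)
}

#' Load the packaged tolerance effect-call table
#'
#' The per-line effect calls (two drugs, with expression-cluster membership
#' and allele class) transcribed from the published mutant-analysis summary
#' shipped with the package.
#'
#' @param path Path to an effect-call TSV; defaults to the packaged table.
#' @return A tibble with `gene`, `cluster`, `allele_class`, `etoh`, `ba`.
#' @export
read_effect_calls <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tolerance_effect_calls.tsv",
                        package = "crosstol", mustWork = TRUE)
  }
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene = readr::col_character(),
                    cluster = readr::col_character(),
                    allele_class = readr::col_character(),
                    etoh = readr::col_character(),
                    ba = readr::col_character()
                  ))
}
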