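# ggplot2 views of the main result types

#' Plot a probe track with optional peaks and ground-truth domains
#'
#' @param track A probe track.
#' @param peaks Optional peak tibble to overlay as shaded intervals.
#' @param truth Optional ground-truth domain tibble (`start`, `end`).
#' @return A ggplot object.
#' @export
plot_track <- function(track, peaks = NULL, truth = NULL) {
  check_track(track)
  p <- ggplot2::ggplot(track, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                           y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = "position (bp)", y = "log2 ratio",
                  title = track_kind(track)) +
    ggplot2::theme_minimal()
  if (!is.null(truth) && nrow(truth) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(truth),
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "goldenrod", alpha = 0.2,
      inherit.aes = FALSE)
  }
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(peaks),
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "firebrick", alpha = 0.25,
      inherit.aes = FALSE)
  }
  p
}

#' @export
autoplot.fdr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$fdr)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "peak-calling threshold (log2 units)",
                  y = "estimated FDR") +
    ggplot2::theme_minimal()
}

#' Heat map of expression profiles in dendrogram order
#'
#' @param expr Expression tibble (`gene_id` + condition columns), typically
#'   row-normalized.
#' @param result A [cut_and_score()] result giving the row order and labels.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(expr, result) {
  stopifnot(inherits(result, "cluster_result"))
  ord <- result$dendrogram$gene_ids[result$dendrogram$hclust$order]
  long <- expr %>%
    tidyr::pivot_longer(-"gene_id", names_to = "condition",
                        values_to = "value") %>%
    mutate(gene_id = factor(.data$gene_id, levels = ord))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "normalized\nexpression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' @export
autoplot.richards_fit <- function(object, ...) {
  grid <- tibble(time_min = seq(min(object$data$time_min),
                                max(object$data$time_min), length.out = 200))
  cf <- object$coefficients
  grid$percent <- richards_curve(grid$time_min, cf["A"], cf["K"], cf["B"],
                                 cf["M"], cf["nu"])
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_min, y = .data$percent)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 50, linetype = 3) +
    ggplot2::labs(x = "time since sedation (min)", y = "% recovered") +
    ggplot2::theme_minimal()
  if (object$t50_defined) {
    p <- p + ggplot2::geom_vline(xintercept = object$t50, linetype = 2)
  }
  p
}

#' @export
autoplot.tolerance_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$line, -.data$delta_t50),
                               y = .data$delta_t50, fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$delta_t50 - .data$se,
                                        ymax = .data$delta_t50 + .data$se),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "tolerance magnitude (min)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
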