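#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X hypergeometric with `K` annotated genes in a universe of
#' `N`, drawing `n` (the cluster size) -- the Fisher-exact enrichment p-value
#' for observing `k` or more annotated genes in the cluster. Vectorized over
#' its arguments.
#'
#' @param k Observed annotated genes in the cluster (0 <= k <= min(n, K)).
#' @param K Annotated genes in the universe.
#' @param n Cluster size.
#' @param N Universe size.
#' @return The tail probability in \[0, 1\].
#' @export
#' @examples
#' hypergeom_tail(3, 4, 5, 20)
hypergeom_tail <- function(k, K, n, N) {
  bad <- k < 0 | k > pmin(n, K) | K > N | n > N | K < 0 | n < 0 | N < 1
  if (any(bad)) abort("infeasible counts: need 0 <= k <= min(n, K), K <= N, n <= N.")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score (jackknifed Fisher exact p-value)
#'
#' The Fisher tail recomputed after removing one annotated gene from the
#' cluster: `hypergeom_tail(max(k - 1, 0), K, n, N)`. Always at least as
#' large as the Fisher p (equal to 1 when k <= 1), making it a conservative
#' enrichment statistic for small clusters.
#'
#' @inheritParams hypergeom_tail
#' @return The EASE p-value.
#' @export
ease_score <- function(k, K, n, N) {
  if (any(k < 0 | k > pmin(n, K) | K > N | n > N)) {
    abort("infeasible counts: need 0 <= k <= min(n, K), K <= N, n <= N.")
  }
  hypergeom_tail(pmax(k - 1, 0), K, n, N)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (one term per line: name, description,
#'   member genes).
#' @return A named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets A named list of gene-id character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bundle annotation sets with their gene universe
#'
#' @param sets A named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe Background gene universe; defaults to the union of all
#'   sets. Every set must be contained in the universe.
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  sets <- map(sets, unique)
  if (is.null(universe)) universe <- unique(unlist(sets))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort("empty universe.")
  stray <- setdiff(unlist(sets), universe)
  if (length(stray) > 0) {
    abort(paste0(length(stray), " set gene(s) missing from the universe."))
  }
  structure(list(sets = sets, universe = universe), class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("<annotation_table> ", length(x$sets), " terms over ",
      length(x$universe), " universe genes\n", sep = "")
  invisible(x)
}

#' Annotation-term enrichment per cluster (Fisher exact + EASE)
#'
#' For every cluster and term, counts the overlap k, computes the Fisher
#' exact tail p and the EASE score, and reports terms with `ease_p < alpha`
#' sorted ascending by EASE score. `percent` is the overlap as a percentage
#' of the cluster size (the Count (%) convention of enrichment tables).
#' Cluster genes outside the universe are reported and dropped. No
#' multiple-testing correction is applied by default (published enrichment
#' tables of this kind print raw scores); Benjamini-Hochberg on the EASE
#' score is available with `adjust = TRUE`.
#'
#' @param clusters A [cut_and_score()] result, or a data frame with
#'   `gene_id`, `cluster`.
#' @param annotations An [annotation_table()].
#' @param alpha Reporting threshold on the (possibly adjusted) EASE score.
#' @param adjust Apply Benjamini-Hochberg across terms within each cluster?
#' @return A tibble with `cluster`, `term`, `k`, `n`, `K`, `N`, `percent`,
#'   `fisher_p`, `ease_p` (and `ease_p_adj` if adjusted).
#' @export
enrich_clusters <- function(clusters, annotations, alpha = 0.05,
                            adjust = FALSE) {
  if (inherits(clusters, "cluster_result")) clusters <- clusters$labels
  stopifnot(is.data.frame(clusters),
            all(c("gene_id", "cluster") %in% names(clusters)))
  stopifnot(inherits(annotations, "annotation_table"))
  universe <- annotations$universe
  N <- length(universe)

  outside <- setdiff(clusters$gene_id, universe)
  if (length(outside) > 0) {
    warn(paste0("dropping ", length(outside),
                " cluster gene(s) absent from the annotation universe."))
    clusters <- clusters %>% filter(.data$gene_id %in% universe)
  }

  K_all <- map_int(annotations$sets, length)
  res <- map(sort(unique(clusters$cluster)), function(cl) {
    members <- clusters$gene_id[clusters$cluster == cl]
    n <- length(members)
    k_all <- map_int(annotations$sets, ~ length(intersect(.x, members)))
    keep <- k_all > 0
    if (!any(keep)) return(NULL)
    kk <- unname(k_all[keep])
    KK <- unname(K_all[keep])
    tibble(cluster = cl, term = names(annotations$sets)[keep],
           k = kk, n = n, K = KK, N = N,
           percent = 100 * kk / n,
           fisher_p = hypergeom_tail(kk, KK, n, N),
           ease_p = ease_score(kk, KK, n, N))
  }) %>% list_rbind()

  if (is.null(res) || nrow(res) == 0) return(res %||% tibble())
  if (adjust) {
    res <- res %>% group_by(.data$cluster) %>%
      mutate(ease_p_adj = stats::p.adjust(.data$ease_p, method = "BH")) %>%
      ungroup()
    res <- res %>% filter(.data$ease_p_adj < alpha)
  } else {
    res <- res %>% filter(.data$ease_p < alpha)
  }
  res %>% arrange(.data$cluster, .data$ease_p, .data$term)
}
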