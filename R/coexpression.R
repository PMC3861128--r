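# split an expression tibble into gene ids + numeric matrix
expr_parts <- function(expr, gene_col = "gene_id") {
  stopifnot(is.data.frame(expr), gene_col %in% names(expr))
  ids <- as.character(expr[[gene_col]])
  mat <- as.matrix(expr[, setdiff(names(expr), gene_col), drop = FALSE])
  if (!is.numeric(mat)) abort("all non-id columns must be numeric expression values.")
  if (anyNA(mat)) abort("expression matrix contains missing values; filter at load time.")
  rownames(mat) <- ids
  list(ids = ids, mat = mat)
}

#' Scale each gene row to unit sum of squares
#'
#' Every row is multiplied by a scale factor S so that the sum of squares of
#' its values is 1 (a separate S per row); the factors are recorded in
#' `attr(, "scale_factors")`. All-zero rows cannot be scaled: they are
#' reported and excluded. The operation is idempotent.
#'
#' @param expr A data frame with a gene id column plus numeric condition
#'   columns.
#' @param gene_col Name of the gene id column.
#' @return The row-normalized tibble.
#' @export
#' @examples
#' normalize_rows(data.frame(gene_id = "g1", c1 = 3, c2 = 4))
normalize_rows <- function(expr, gene_col = "gene_id") {
  p <- expr_parts(expr, gene_col)
  ss <- rowSums(p$mat^2)
  zero <- ss == 0
  if (any(zero)) {
    warn(paste0("excluding ", sum(zero), " all-zero row(s): ",
                paste(p$ids[zero], collapse = ", ")))
  }
  keep <- !zero
  S <- unname(1 / sqrt(ss[keep]))
  scaled <- p$mat[keep, , drop = FALSE] * S
  out <- bind_cols(tibble(!!gene_col := p$ids[keep]),
                   as_tibble(as.data.frame(scaled)))
  attr(out, "scale_factors") <- tibble(!!gene_col := p$ids[keep], scale_factor = S)
  attr(out, "dropped") <- p$ids[zero]
  out
}

#' Centered Pearson correlation between two expression profiles
#'
#' The standard mean-centered Pearson correlation; the clustering distance
#' used downstream is `1 - r`. Errors on zero-variance profiles rather than
#' returning NA.
#'
#' @param x,y Numeric profiles of equal length >= 2.
#' @return The correlation r in \[-1, 1\].
#' @export
centered_pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("profiles must have equal length >= 2.")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance profile.")
  cor(x, y)
}

#' Seed gene ordering with a 1-D self-organizing map
#'
#' Trains a one-dimensional SOM of `k` nodes on the (normalized) expression
#' rows with correlation-based matching (distance `1 - r` to each node
#' prototype), a shrinking bubble neighborhood, and a linearly decaying
#' learning rate. The node assignment is used only to order rows before
#' hierarchical clustering, mirroring the SOM-then-tree workflow of classic
#' expression-clustering programs.
#'
#' @param expr Expression tibble (normalize with [normalize_rows()] first).
#' @param k Number of nodes (default 10; must not exceed the gene count).
#' @param steps Presentation steps (default 20000).
#' @param lr Learning rate at the first and last step (default 0.02 -> 0.001).
#' @param gene_col Name of the gene id column.
#' @param seed Integer seed (fixed seed gives identical assignments).
#' @return A tibble `gene_id`, `node`, with the node prototype matrix in
#'   `attr(, "codes")`.
#' @export
som_seed <- function(expr, k = 10, steps = 20000, lr = c(0.02, 0.001),
                     gene_col = "gene_id", seed = 1) {
  p <- expr_parts(expr, gene_col)
  n <- nrow(p$mat)
  k <- check_count(k, "k")
  if (k > n) abort("`k` must not exceed the number of genes.")
  steps <- check_count(steps, "steps")
  set.seed(seed)

  # row-standardize once so matching by correlation is a dot product
  z <- t(scale(t(p$mat)))
  if (anyNA(z)) abort("zero-variance gene profile; drop constant rows first.")
  nc <- ncol(z)
  z <- z / sqrt(rowSums(z^2))

  codes <- z[sample.int(n, k), , drop = FALSE] +
    matrix(rnorm(k * nc, 0, 1e-3), nrow = k)
  alpha <- seq(lr[1], lr[2], length.out = steps)
  radius <- seq(max(k / 2, 1), 0.5, length.out = steps)
  pick <- sample.int(n, steps, replace = TRUE)
  for (s in seq_len(steps)) {
    x <- z[pick[s], ]
    sims <- codes %*% x / sqrt(rowSums(codes^2))
    win <- which.max(sims)
    neigh <- which(abs(seq_len(k) - win) <= radius[s])
    codes[neigh, ] <- codes[neigh, ] +
      alpha[s] * (matrix(x, nrow = length(neigh), ncol = nc, byrow = TRUE) -
                    codes[neigh, , drop = FALSE])
  }
  sims <- (z %*% t(codes)) / matrix(sqrt(rowSums(codes^2)), nrow = n, ncol = k, byrow = TRUE)
  node <- apply(sims, 1, which.max)
  out <- tibble(!!gene_col := p$ids, node = as.integer(node))
  attr(out, "codes") <- codes
  out
}

#' Complete-linkage hierarchical clustering on centered-Pearson distance
#'
#' Builds the agglomerative complete-linkage tree on distance `1 - r` between
#' gene expression profiles. If a SOM assignment is supplied, the dendrogram
#' leaves are reordered to follow the SOM node order wherever the tree
#' topology permits (cluster membership is unaffected).
#'
#' @param expr Expression tibble (normalized rows recommended).
#' @param som Optional [som_seed()] result used as a leaf-order hint.
#' @param linkage Agglomeration method (default `"complete"`; `"single"` and
#'   `"average"` are available for robustness checks).
#' @param gene_col Name of the gene id column.
#' @return An object of class `coexpr_clust`: `$hclust`, `$cor` (gene-gene
#'   correlation matrix), `$gene_ids`, `$linkage`.
#' @export
hierarchical_cluster <- function(expr, som = NULL,
                                 linkage = c("complete", "single", "average"),
                                 gene_col = "gene_id") {
  linkage <- match.arg(linkage)
  p <- expr_parts(expr, gene_col)
  if (nrow(p$mat) < 2) abort("need at least 2 genes to cluster.")
  R <- cor(t(p$mat))
  hc <- hclust(as.dist(1 - R), method = linkage)
  hc$labels <- p$ids
  if (!is.null(som)) {
    wts <- som$node[match(p$ids, som[[gene_col]])]
    if (anyNA(wts)) abort("SOM assignment does not cover all genes.")
    dend <- reorder(as.dendrogram(hc), wts = wts, agglo.FUN = mean)
    hc$order <- order.dendrogram(dend)
  }
  structure(list(hclust = hc, cor = R, mat = p$mat, gene_ids = p$ids,
                 linkage = linkage, som = som),
            class = "coexpr_clust")
}

#' @export
print.coexpr_clust <- function(x, ...) {
  cat("<coexpr_clust> ", length(x$gene_ids), " genes, ", x$linkage,
      " linkage on 1 - centered Pearson",
      if (!is.null(x$som)) ", SOM-ordered leaves", "\n", sep = "")
  invisible(x)
}

#' Cut the tree and score cluster cohesion
#'
#' Cuts the dendrogram into `k` clusters and scores each cluster's cohesion
#' as the mean pairwise centered Pearson correlation over all member pairs
#' (the conservative reading of a single per-cluster r; correlation to the
#' cluster centroid is available via `method = "centroid"`). Clusters with
#' cohesion above `cohesion_threshold` are flagged highly correlated;
#' singletons have undefined cohesion and are flagged NA.
#'
#' @param clust A [hierarchical_cluster()] result.
#' @param k Number of clusters (default 7).
#' @param cohesion_threshold Flagging threshold on cohesion r (default 0.65).
#' @param method `"pairwise"` (default) or `"centroid"`.
#' @return An object of class `cluster_result`: `$labels` (tibble `gene_id`,
#'   `cluster`), `$clusters` (tibble `cluster`, `n_genes`, `cohesion`,
#'   `highly_correlated`), `$k`, `$dendrogram`.
#' @export
cut_and_score <- function(clust, k = 7, cohesion_threshold = 0.65,
                          method = c("pairwise", "centroid")) {
  stopifnot(inherits(clust, "coexpr_clust"))
  method <- match.arg(method)
  n <- length(clust$gene_ids)
  k <- check_count(k, "k")
  if (k > n) abort("`k` must not exceed the number of genes.")
  labels <- cutree(clust$hclust, k = k)

  cohesion_of <- function(members) {
    if (length(members) < 2) return(NA_real_)
    if (method == "pairwise") {
      sub <- clust$cor[members, members]
      mean(sub[lower.tri(sub)])
    } else {
      centroid <- colMeans(clust$mat[members, , drop = FALSE])
      mean(apply(clust$mat[members, , drop = FALSE], 1, cor, y = centroid))
    }
  }

  summary <- map(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    r <- cohesion_of(members)
    tibble(cluster = cl, n_genes = length(members), cohesion = r,
           highly_correlated = if (is.na(r)) NA else r > cohesion_threshold)
  }) %>% list_rbind()

  structure(
    list(labels = tibble(gene_id = clust$gene_ids, cluster = unname(labels)),
         clusters = summary, k = k, cohesion_threshold = cohesion_threshold,
         dendrogram = clust),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k = ", x$k, "; ",
      sum(x$clusters$highly_correlated, na.rm = TRUE),
      " cluster(s) with cohesion r > ", x$cohesion_threshold, "\n", sep = "")
  print(x$clusters)
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  left_join(x$labels, x$clusters, by = "cluster")
}

#' @export
glance.cluster_result <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$labels),
         n_highly_correlated = sum(x$clusters$highly_correlated, na.rm = TRUE),
         mean_cohesion = mean(x$clusters$cohesion, na.rm = TRUE))
}

#' Cohesion profile over a range of tree cuts
#'
#' The cut level that separates "distinct" clusters is a judgment call; this
#' report lists per-cluster cohesion for each k in `k_range` so patterns such
#' as "4 of 7 clusters highly correlated" can be inspected directly.
#'
#' @inheritParams cut_and_score
#' @param k_range Integer vector of cut levels.
#' @return A tibble with `k`, `cluster`, `n_genes`, `cohesion`,
#'   `highly_correlated`.
#' @export
cohesion_scan <- function(clust, k_range = 2:10, cohesion_threshold = 0.65) {
  map(k_range, function(k) {
    cut_and_score(clust, k = k, cohesion_threshold = cohesion_threshold)$clusters %>%
      mutate(k = k) %>% relocate("k")
  }) %>% list_rbind()
}
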