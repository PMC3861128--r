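#' Simulate a block-correlated genes-by-conditions expression matrix
#'
#' Each cluster of genes shares one latent condition profile; gene rows are
#' the latent profile plus independent Gaussian noise whose sd is chosen so
#' the expected within-cluster Pearson correlation equals `r_within`
#' (`noise_sd = sqrt(1/r - 1)` on the unit-variance latent scale), then each
#' gene gets its own positive scale and baseline offset (Pearson correlation
#' is blind to both). Latent profiles of different clusters are drawn mutually
#' orthogonal, so the expected between-cluster correlation is ~0.
#'
#' @param cluster_sizes Integer vector of genes per cluster; the matrix has
#'   `sum(cluster_sizes)` rows.
#' @param n_conditions Number of conditions (columns; default 21, the number
#'   of environmental treatment profiles the pipeline is designed around).
#' @param r_within Target expected within-cluster Pearson correlation in (0, 1].
#' @param noise_sd Optional override for the latent-scale noise sd; by default
#'   derived from `r_within`.
#' @param seed Integer seed.
#'
#' @return An object of class `expr_sim`: `$expression` (tibble, `gene_id`
#'   plus one column per condition), `$labels` (tibble: `gene_id`, `cluster`),
#'   `$params`.
#' @export
#' @examples
#' sim <- simulate_expression_matrix(c(10, 10), r_within = 0.9, seed = 1)
#' dim(sim$expression)
simulate_expression_matrix <- function(cluster_sizes, n_conditions = 21,
                                       r_within = 0.8, noise_sd = NULL,
                                       seed = 1) {
  if (length(cluster_sizes) < 1 || any(cluster_sizes < 1)) {
    abort("`cluster_sizes` must be positive gene counts.")
  }
  n_conditions <- check_count(n_conditions, "n_conditions", min = 2)
  r_within <- check_number(r_within, "r_within", min = 0, max = 1, strict_min = TRUE)
  n_clusters <- length(cluster_sizes)
  if (n_clusters > n_conditions) {
    abort("cannot draw more mutually orthogonal latent profiles than conditions.")
  }
  if (is.null(noise_sd)) noise_sd <- sqrt(1 / r_within - 1)
  set.seed(seed)

  raw <- matrix(rnorm(n_conditions * n_clusters), nrow = n_conditions)
  latents <- qr.Q(qr(raw))[, seq_len(n_clusters), drop = FALSE]
  latents <- apply(latents, 2, function(z) (z - mean(z)) / sd(z))
  latents <- matrix(latents, nrow = n_conditions)

  n_genes <- sum(cluster_sizes)
  labels <- rep(seq_len(n_clusters), cluster_sizes)
  baseline <- runif(n_genes, 2, 8)
  scale_i <- runif(n_genes, 0.5, 2)
  mat <- matrix(0, nrow = n_genes, ncol = n_conditions)
  for (i in seq_len(n_genes)) {
    mat[i, ] <- baseline[i] +
      scale_i[i] * (latents[, labels[i]] + noise_sd * rnorm(n_conditions))
  }
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  cond_ids <- sprintf("cond_%02d", seq_len(n_conditions))
  expr <- as_tibble(setNames(as.data.frame(mat), cond_ids))
  expr <- bind_cols(tibble(gene_id = gene_ids), expr)

  structure(
    list(expression = expr,
         labels = tibble(gene_id = gene_ids, cluster = labels),
         params = list(cluster_sizes = cluster_sizes,
                       n_conditions = n_conditions, r_within = r_within,
                       noise_sd = noise_sd, seed = seed)),
    class = "expr_sim"
  )
}

#' @export
print.expr_sim <- function(x, ...) {
  cat("<expr_sim> ", nrow(x$expression), " genes x ",
      x$params$n_conditions, " conditions in ",
      length(x$params$cluster_sizes), " clusters (target r ",
      x$params$r_within, ")\n", sep = "")
  invisible(x)
}
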