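#' Default pipeline configuration
#'
#' All stage parameters in one auditable list, with defaults matching the
#' analysis the package implements: FDR cutoff 0.05, enrichment-score cutoff
#' 0.5, 500-bp bidirectional assignment pad, cluster-cohesion threshold 0.65,
#' enrichment alpha 0.05. The `simulation` block describes the bundled
#' synthetic demo (used when no input paths are given).
#'
#' @param seed Integer seed driving every stochastic stage.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    simulation = list(
      n_genes = 60, chrom_length = 800000, probe_spacing = 55,
      n_shared = 12, n_a_only = 10, n_b_only = 10,
      domain_width = 1000, effect = 1.0, noise_sd = 0.5,
      n_replicates = 2, baseline_effect = 0.8
    ),
    peaks = list(fdr_cutoff = 0.05, enrichment_cutoff = 0.5,
                 min_probes = 4, max_gap = 150, n_permutations = 100),
    mapping = list(pad = 500),
    expression = list(n_conditions = 21, r_within = 0.8, n_clusters = 4),
    clustering = list(k = 4, cohesion_threshold = 0.65,
                      som_k = 10, som_steps = 2000),
    enrichment = list(alpha = 0.05, n_background_terms = 10)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default, so a config file only needs to name what it changes.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding both default and file.
#' @return A `run_config` list.
#' @export
read_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  cfg <- merge_into(unclass(cfg), user)
  if (!is.null(seed)) cfg$seed <- seed
  structure(cfg, class = "run_config")
}

# synthetic per-cluster annotation sets for the bundled demo: one term
# planted per expression cluster plus random background terms
demo_annotations <- function(labels, n_background = 10, seed = 1) {
  set.seed(seed)
  universe <- labels$gene_id
  sets <- list()
  for (cl in sort(unique(labels$cluster))) {
    members <- labels$gene_id[labels$cluster == cl]
    extra <- sample(setdiff(universe, members),
                    min(2, length(setdiff(universe, members))))
    sets[[sprintf("planted_term_cluster_%d", cl)]] <- c(members, extra)
  }
  for (b in seq_len(n_background)) {
    sets[[sprintf("background_term_%02d", b)]] <-
      sample(universe, max(3, rpois(1, length(universe) / 5)))
  }
  annotation_table(sets, universe = universe)
}

#' Run the full cross-drug tolerance-gene discovery pipeline
#'
#' Executes the analysis end to end on simulated (or user-supplied) inputs:
#' simulate the tiling experiment, build replicate-averaged drug-vs-control
#' difference tracks, estimate the permutation FDR curve and call peaks per
#' drug, assign peaks to genes by the bidirectional distance rule, rank and
#' intersect the two drug cohorts, cluster the common genes by their
#' condition-expression profiles, and score annotation-term enrichment per
#' cluster. Reruns with the same config and seed reproduce identical outputs
#' byte for byte.
#'
#' @param config A [default_config()] / [read_config()] list.
#' @param outdir Optional output directory; when given, every stage result is
#'   written (bedGraph, BED, TSV, Newick, JSON) and checksummed in the report.
#' @param seed Overrides `config$seed` when given.
#' @return A `crosstol_report` list: effective config, per-stage summaries,
#'   cohort sizes, intersection, clustering and enrichment results, the
#'   recovered-vs-planted Jaccard index (simulation runs), and file
#'   checksums (when `outdir` is used).
#' @export
run_tolerance_pipeline <- function(config = default_config(), outdir = NULL,
                                   seed = NULL) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  if (!is.null(seed)) config$seed <- seed
  base_seed <- check_count(config$seed, "config$seed", min = 0)
  report <- list(config = unclass(config), stages = list())
  files <- character(0)

  # --- stage 1: simulate -----------------------------------------------
  sim_cfg <- config$simulation
  genome <- make_toy_genome(sim_cfg$n_genes, sim_cfg$chrom_length,
                            probe_spacing = sim_cfg$probe_spacing,
                            seed = derive_seed(base_seed, 1))
  set.seed(derive_seed(base_seed, 2))
  n_spiked <- sim_cfg$n_shared + sim_cfg$n_a_only + sim_cfg$n_b_only
  if (n_spiked > nrow(genome$genes)) abort("more spiked genes than genes.")
  picked <- sample(genome$genes$gene_id, n_spiked)
  spikes <- spike_spec(
    shared = picked[seq_len(sim_cfg$n_shared)],
    a_only = picked[sim_cfg$n_shared + seq_len(sim_cfg$n_a_only)],
    b_only = picked[sim_cfg$n_shared + sim_cfg$n_a_only + seq_len(sim_cfg$n_b_only)],
    width = sim_cfg$domain_width, effect = sim_cfg$effect
  )
  sim <- simulate_tiling_experiment(
    genome, spikes, noise_sd = sim_cfg$noise_sd,
    n_replicates = sim_cfg$n_replicates,
    baseline_effect = sim_cfg$baseline_effect,
    seed = derive_seed(base_seed, 3)
  )
  report$stages$simulate <- list(n_probes = nrow(genome$probes),
                                 n_genes = nrow(genome$genes),
                                 n_planted_domains = nrow(sim$truth$domains))

  # --- stage 2 + 3: difference tracks and peak calling per drug --------
  pk <- config$peaks
  drug_results <- list()
  for (drug in c("A", "B")) {
    track <- difference_from_sim(sim, drug)
    curve <- estimate_fdr(track, n_permutations = pk$n_permutations,
                          min_probes = pk$min_probes, max_gap = pk$max_gap,
                          seed = derive_seed(base_seed, 10 + match(drug, c("A", "B"))))
    peaks <- select_peaks(track, curve, fdr_cutoff = pk$fdr_cutoff,
                          enrichment_cutoff = pk$enrichment_cutoff,
                          min_probes = pk$min_probes, max_gap = pk$max_gap)
    drug_results[[drug]] <- list(track = track, curve = curve, peaks = peaks)
    report$stages[[paste0("peaks_", drug)]] <-
      list(threshold = attr(peaks, "threshold"),
           n_peaks = nrow(peaks),
           reason = attr(peaks, "reason"))
  }

  # --- stage 4: gene mapping and intersection --------------------------
  genes <- collapse_isoforms(genome$genes)
  cohorts <- list()
  for (drug in c("A", "B")) {
    asn <- assign_peaks(drug_results[[drug]]$peaks, genes,
                        pad = config$mapping$pad)
    cohorts[[drug]] <- build_cohort(asn, drug_label = drug)
    drug_results[[drug]]$assignments <- asn
  }
  inter <- intersect_cohorts(cohorts$A, cohorts$B)
  report$stages$intersection <- as.list(inter$summary)

  truth_shared <- sim$truth$shared
  recovered <- inter$genes$gene_id
  jacc <- length(intersect(recovered, truth_shared)) /
    max(1, length(union(recovered, truth_shared)))
  report$jaccard_shared <- jacc
  report$truth <- list(shared = truth_shared,
                       a_only = sim$truth$a_only, b_only = sim$truth$b_only)

  # --- stage 5: co-expression clustering of the common genes -----------
  clustering_done <- length(recovered) >= max(4, config$clustering$k)
  clust_result <- NULL
  expr_norm <- NULL
  expr_labels <- NULL
  if (clustering_done) {
    ex_cfg <- config$expression
    sizes <- diff(round(seq(0, length(recovered), length.out = ex_cfg$n_clusters + 1)))
    sizes <- sizes[sizes > 0]
    ex <- simulate_expression_matrix(sizes, n_conditions = ex_cfg$n_conditions,
                                     r_within = ex_cfg$r_within,
                                     seed = derive_seed(base_seed, 20))
    # carry the recovered gene ids (sorted by mean rank) onto the simulated rows
    ex$expression$gene_id <- recovered
    ex$labels$gene_id <- recovered
    expr_labels <- ex$labels
    expr_norm <- normalize_rows(ex$expression)
    som <- som_seed(expr_norm, k = min(config$clustering$som_k, nrow(expr_norm)),
                    steps = config$clustering$som_steps,
                    seed = derive_seed(base_seed, 21))
    tree <- hierarchical_cluster(expr_norm, som = som)
    clust_result <- cut_and_score(tree, k = min(config$clustering$k, nrow(expr_norm)),
                                  cohesion_threshold = config$clustering$cohesion_threshold)
    report$stages$clustering <- list(
      k = clust_result$k,
      cohesion = clust_result$clusters$cohesion,
      n_highly_correlated = sum(clust_result$clusters$highly_correlated, na.rm = TRUE))
  } else {
    report$stages$clustering <- list(skipped = "too few common genes to cluster")
  }

  # --- stage 6: enrichment ---------------------------------------------
  enrich_result <- NULL
  if (clustering_done) {
    ann <- demo_annotations(clust_result$labels,
                            n_background = config$enrichment$n_background_terms,
                            seed = derive_seed(base_seed, 30))
    enrich_result <- enrich_clusters(clust_result, ann,
                                     alpha = config$enrichment$alpha)
    report$stages$enrichment <- list(n_significant_terms = nrow(enrich_result))
  } else {
    report$stages$enrichment <- list(skipped = "no clusters")
  }

  # --- stage 7: write outputs and checksum ------------------------------
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(...) file.path(outdir, paste0(...))
    write_gff3_genes(genome$genes, fp("genes.gff3")); files <- c(files, fp("genes.gff3"))
    for (drug in c("A", "B")) {
      write_track(drug_results[[drug]]$track, fp("difference_", drug, ".bedgraph"))
      readr::write_tsv(drug_results[[drug]]$curve, fp("fdr_curve_", drug, ".tsv"))
      write_bed_peaks(drug_results[[drug]]$peaks, fp("peaks_", drug, ".bed"))
      readr::write_tsv(drug_results[[drug]]$assignments, fp("assignments_", drug, ".tsv"))
      readr::write_tsv(cohorts[[drug]], fp("cohort_", drug, ".tsv"))
      files <- c(files, fp("difference_", drug, ".bedgraph"),
                 fp("fdr_curve_", drug, ".tsv"), fp("peaks_", drug, ".bed"),
                 fp("assignments_", drug, ".tsv"), fp("cohort_", drug, ".tsv"))
    }
    readr::write_tsv(inter$genes, fp("intersection_genes.tsv"))
    jsonlite::write_json(c(as.list(inter$summary), jaccard_shared = jacc),
                         fp("intersection_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, fp("intersection_genes.tsv"), fp("intersection_summary.json"))
    if (clustering_done) {
      readr::write_tsv(clust_result$labels, fp("cluster_labels.tsv"))
      readr::write_tsv(clust_result$clusters, fp("cluster_cohesion.tsv"))
      write_newick(clust_result$dendrogram, fp("dendrogram.nwk"))
      readr::write_tsv(enrich_result, fp("enrichment.tsv"))
      files <- c(files, fp("cluster_labels.tsv"), fp("cluster_cohesion.tsv"),
                 fp("dendrogram.nwk"), fp("enrichment.tsv"))
    }
    report$files <- tibble(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(
      report[setdiff(names(report), "files")],
      file.path(outdir, "run_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }

  report$cohorts <- cohorts
  report$intersection <- inter
  report$clustering <- clust_result
  report$enrichment <- enrich_result
  report$expression <- expr_norm
  report$expression_truth <- expr_labels
  structure(report, class = "crosstol_report")
}

#' @export
print.crosstol_report <- function(x, ...) {
  s <- x$stages$intersection
  cat("<crosstol_report>\n")
  cat("  cohorts: |A| = ", s$n_a, ", |B| = ", s$n_b,
      ", common = ", s$n_common, "\n", sep = "")
  if (!is.null(x$jaccard_shared)) {
    cat(sprintf("  Jaccard vs planted shared set: %.3f\n", x$jaccard_shared))
  }
  cl <- x$stages$clustering
  if (is.null(cl$skipped)) {
    cat("  clusters: k = ", cl$k, ", highly correlated = ",
        cl$n_highly_correlated, "\n", sep = "")
  } else {
    cat("  clustering skipped:", cl$skipped, "\n")
  }
  invisible(x)
}
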