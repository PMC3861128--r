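# File I/O. Internal coordinates are 0-based half-open everywhere; GFF3
# (1-based inclusive) and BED/bedGraph (0-based half-open) convert at the
# boundary, so the 500-bp distance rule is free of off-by-one ambiguity.

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = if ("strand" %in% names(genes)) genes$strand else "*",
    ID = genes$gene_id
  )
}

#' Write gene models to GFF3
#'
#' @param genes A gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`;
#'   0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  gr <- genes_to_granges(genes)
  gr$type <- "gene"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 rows of type `gene` (all rows when no type column is present) are
#' converted to the package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 or BED file.
#' @return A gene tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  if ("type" %in% names(md)) gr <- gr[as.character(gr$type) == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID)
         else if (!is.null(gr$name)) as.character(gr$name)
         else paste0("gene_", seq_along(gr))
  tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) %>% mutate(strand = ifelse(.data$strand == "*", "+", .data$strand))
}

#' Write gene models to BED12 (single-block genes)
#'
#' @inheritParams write_gff3_genes
#' @export
write_bed12_genes <- function(genes, path) {
  bed <- tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = 0L,
    strand = if ("strand" %in% names(genes)) genes$strand else ".",
    thick_start = genes$start, thick_end = genes$end, rgb = "0,0,0",
    block_count = 1L, block_sizes = paste0(genes$end - genes$start, ","),
    block_starts = "0,"
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a probe track to bedGraph with a provenance sidecar
#'
#' The track's normalization parameters (`attr(, "params")` and kind) go to
#' `<path>.json` so every written track carries its provenance.
#'
#' @param track A probe track.
#' @param path Output path (bedGraph).
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  check_track(track)
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  sidecar <- list(kind = track_kind(track),
                  n_probes = nrow(track),
                  params = attr(track, "params"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a probe track from bedGraph
#'
#' @param path Path to a 4-column bedGraph.
#' @param kind Track kind to record.
#' @return A probe track tibble.
#' @export
read_track <- function(path, kind = "ip_over_input") {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        comment = "#", show_col_types = FALSE)
  df <- df[!grepl("^track", df$chrom), ]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$value <- as.numeric(df$value)
  out <- new_track(df, df$value, kind = kind)
  check_track(out)
  out
}

#' Write a peak set to BED6 plus a statistics TSV
#'
#' The BED score column is `round(1000 * enrichment_score)` clamped to
#' \[0, 1000\]; the companion `<path>.stats.tsv` carries magnitude,
#' enrichment score, FDR and probe count per peak.
#'
#' @param peaks A [select_peaks()] result.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed_peaks <- function(peaks, path) {
  score <- if ("enrichment_score" %in% names(peaks)) {
    pmin(pmax(round(1000 * peaks$enrichment_score), 0), 1000)
  } else 0L
  bed <- tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                name = sprintf("peak_%d", seq_len(nrow(peaks))),
                score = as.integer(score), strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  readr::write_tsv(as_tibble(peaks), paste0(path, ".stats.tsv"))
  invisible(path)
}

#' Write/read an expression matrix TSV (gene rows, condition columns)
#'
#' @param expr Expression tibble with a `gene_id` column.
#' @param path File path.
#' @return `path` (write) or the expression tibble (read).
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write/read a sedation-recovery TSV
#'
#' Columns: `line`, `group`, `vial`, `time_min`, `n_recovered`, `n_total`.
#'
#' @param recovery Recovery tibble.
#' @param path File path.
#' @export
write_recovery_tsv <- function(recovery, path) {
  readr::write_tsv(recovery, path)
  invisible(path)
}

#' @rdname write_recovery_tsv
#' @export
read_recovery_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Export a clustering dendrogram to Newick
#'
#' Leaf names are gene ids; branch lengths derive from the complete-linkage
#' merge heights on the `1 - r` scale.
#'
#' @param clust A [hierarchical_cluster()] result.
#' @param path Output path.
#' @export
write_newick <- function(clust, path) {
  stopifnot(inherits(clust, "coexpr_clust"))
  ape::write.tree(ape::as.phylo(clust$hclust), file = path)
  invisible(path)
}
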