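#' Collapse isoform annotations to one span per gene
#'
#' Multiple annotated spans of one gene id are merged to a single region from
#' the 5'-most start to the 3'-most end before mapping, matching the working
#' definition of a gene region (5'-most transcriptional start site to the end
#' of the 3' UTR).
#'
#' @param genes A data frame with `gene_id`, `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @return A tibble with one row per gene id.
#' @export
collapse_isoforms <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  genes %>%
    group_by(.data$gene_id, .data$chrom) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              strand = if ("strand" %in% names(genes)) first(.data$strand) else "+",
              .groups = "drop")
}

#' Pad gene spans bidirectionally for peak assignment
#'
#' Each gene's query interval is its span extended by `pad` bp on both sides
#' (clipped at 0). Padding ignores strand: the distance rule is bidirectional.
#'
#' @inheritParams collapse_isoforms
#' @param pad Padding in bp (default 500).
#' @return The gene tibble with added `query_start`, `query_end` columns.
#' @export
#' @examples
#' extend_gene_regions(data.frame(gene_id = "g", chrom = "c",
#'                                start = 1000, end = 2000))
extend_gene_regions <- function(genes, pad = 500) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  pad <- check_number(pad, "pad", min = 0)
  genes %>%
    as_tibble() %>%
    mutate(query_start = pmax(.data$start - pad, 0),
           query_end = .data$end + pad)
}

# distance from a point to a 0-based half-open interval (0 when inside)
point_to_span <- function(p, s, e) pmax(s - p, p - (e - 1), 0)

#' Assign peaks to nearby genes by the bidirectional distance rule
#'
#' A peak is assigned to the gene(s) whose span lies within `pad` bp of the
#' peak (distance 0 when peak and gene span overlap). When several genes are
#' at the minimal distance -- typically a peak overlapping two adjacent gene
#' spans -- the gene whose unextended span is nearest to the peak midpoint
#' wins; exact midpoint ties assign the peak to all tied genes and flag them,
#' rather than silently dropping a potential target. Peaks with no gene
#' within `pad` bp are returned with `gene_id = NA` so they stay visible.
#'
#' @param peaks A peak data frame (`chrom`, `start`, `end`, and optionally
#'   `magnitude`).
#' @param genes A gene data frame (`gene_id`, `chrom`, `start`, `end`);
#'   isoforms should be collapsed first (see [collapse_isoforms()]).
#' @param pad Maximum assignment distance in bp (default 500).
#'
#' @return A tibble with one row per (peak, assigned gene): `peak_id`,
#'   `chrom`, `peak_start`, `peak_end`, `magnitude` (NA if absent),
#'   `gene_id`, `distance`, `tied`.
#' @export
assign_peaks <- function(peaks, genes, pad = 500) {
  stopifnot(is.data.frame(peaks),
            all(c("chrom", "start", "end") %in% names(peaks)))
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  pad <- check_number(pad, "pad", min = 0)

  pk <- as_tibble(peaks) %>%
    mutate(peak_id = row_number(),
           magnitude = if ("magnitude" %in% names(peaks)) .data$magnitude else NA_real_) %>%
    select("peak_id", "chrom", peak_start = "start", peak_end = "end", "magnitude")
  gn <- as_tibble(genes) %>%
    select("gene_id", "chrom", gene_start = "start", gene_end = "end")

  cand <- inner_join(pk, gn, by = "chrom", relationship = "many-to-many") %>%
    mutate(distance = interval_distance(.data$peak_start, .data$peak_end,
                                        .data$gene_start, .data$gene_end)) %>%
    filter(.data$distance <= pad)

  if (nrow(cand) == 0) {
    return(pk %>% mutate(gene_id = NA_character_, distance = NA_real_,
                         tied = FALSE))
  }

  assigned <- cand %>%
    group_by(.data$peak_id) %>%
    filter(.data$distance == min(.data$distance)) %>%
    mutate(
      mid = .data$peak_start + floor((.data$peak_end - .data$peak_start) / 2),
      mid_distance = point_to_span(.data$mid, .data$gene_start, .data$gene_end)
    ) %>%
    filter(.data$mid_distance == min(.data$mid_distance)) %>%
    mutate(tied = n() > 1) %>%
    ungroup() %>%
    select("peak_id", "chrom", "peak_start", "peak_end", "magnitude",
           "gene_id", "distance", "tied")

  unassigned <- pk %>%
    filter(!.data$peak_id %in% assigned$peak_id) %>%
    mutate(gene_id = NA_character_, distance = NA_real_, tied = FALSE)

  bind_rows(assigned, unassigned) %>% arrange(.data$peak_id, .data$gene_id)
}

#' Build a ranked gene cohort for one drug
#'
#' One entry per assigned gene, scored by its best (maximum) peak magnitude
#' and rank-ordered by descending magnitude; the number of contributing peaks
#' is reported as multiplicity. Magnitude ties break alphabetically by gene
#' id so ranks are deterministic.
#'
#' @param assignments An [assign_peaks()] result.
#' @param drug_label Label recorded in the `drug` column.
#' @return A tibble of class `gene_cohort`: `drug`, `gene_id`, `magnitude`,
#'   `n_peaks`, `rank`.
#' @export
build_cohort <- function(assignments, drug_label = "drug") {
  stopifnot(is.data.frame(assignments),
            all(c("gene_id", "magnitude") %in% names(assignments)))
  hits <- assignments %>% filter(!is.na(.data$gene_id))
  if (nrow(hits) == 0) {
    out <- tibble(drug = character(), gene_id = character(),
                  magnitude = numeric(), n_peaks = integer(), rank = integer())
    class(out) <- c("gene_cohort", class(out))
    return(out)
  }
  out <- hits %>%
    group_by(.data$gene_id) %>%
    summarise(magnitude = max(.data$magnitude), n_peaks = n(), .groups = "drop") %>%
    arrange(desc(.data$magnitude), .data$gene_id) %>%
    mutate(drug = drug_label, rank = row_number()) %>%
    relocate("drug")
  class(out) <- c("gene_cohort", class(out))
  out
}

#' Intersect two drugs' gene cohorts
#'
#' Set intersection by gene id, ordered best-first by the mean of the two
#' per-drug ranks. The summary reports both cohort sizes, the intersection
#' size, and the overlap as a fraction of the mean cohort size as well as of
#' each cohort.
#'
#' @param a,b [build_cohort()] results.
#' @return An object of class `cohort_intersection`: `$genes` (tibble:
#'   `gene_id`, per-drug magnitudes and ranks, `mean_rank`) and `$summary`
#'   (one-row tibble: `n_a`, `n_b`, `n_common`, `overlap_fraction`,
#'   `fraction_of_a`, `fraction_of_b`).
#' @export
intersect_cohorts <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  common <- inner_join(
    a %>% select("gene_id", magnitude_a = "magnitude", rank_a = "rank"),
    b %>% select("gene_id", magnitude_b = "magnitude", rank_b = "rank"),
    by = "gene_id"
  ) %>%
    mutate(mean_rank = (.data$rank_a + .data$rank_b) / 2) %>%
    arrange(.data$mean_rank, .data$gene_id)
  n_a <- nrow(a); n_b <- nrow(b); n_common <- nrow(common)
  summary <- tibble(
    n_a = n_a, n_b = n_b, n_common = n_common,
    overlap_fraction = if (n_a + n_b > 0) n_common / mean(c(n_a, n_b)) else 0,
    fraction_of_a = if (n_a > 0) n_common / n_a else 0,
    fraction_of_b = if (n_b > 0) n_common / n_b else 0
  )
  structure(list(genes = common, summary = summary),
            class = "cohort_intersection")
}

#' @export
print.cohort_intersection <- function(x, ...) {
  s <- x$summary
  cat("<cohort_intersection> |A| = ", s$n_a, ", |B| = ", s$n_b,
      ", |A n B| = ", s$n_common,
      sprintf(" (%.1f%% of mean cohort size)\n", 100 * s$overlap_fraction),
      sep = "")
  invisible(x)
}

#' @export
glance.cohort_intersection <- function(x, ...) x$summary
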