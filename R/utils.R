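# internal helpers shared across modules

# validate a probe-signal track: tibble with chrom, start, end, value
check_track <- function(track, arg = "track") {
  if (!is.data.frame(track)) {
    abort(sprintf("`%s` must be a data frame with columns chrom, start, end, value.", arg))
  }
  need <- c("chrom", "start", "end", "value")
  missing_cols <- setdiff(need, names(track))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(track) == 0) return(invisible(track))
  if (length(unique(track$chrom)) > 1) {
    abort(sprintf("`%s` must hold a single chromosome; split multi-chromosome data first.", arg))
  }
  if (any(!is.finite(track$value))) {
    abort(sprintf("`%s` contains non-finite values; masked probes must be dropped, not kept as NA.", arg))
  }
  if (is.unsorted(track$start, strictly = TRUE)) {
    abort(sprintf("probe starts in `%s` must be strictly increasing.", arg))
  }
  if (any(track$end <= track$start)) {
    abort(sprintf("every probe in `%s` needs end > start (0-based half-open).", arg))
  }
  invisible(track)
}

# do two tracks share an identical probe grid?
same_grid <- function(a, b) {
  nrow(a) == nrow(b) &&
    identical(a$chrom, b$chrom) &&
    identical(a$start, b$start) &&
    identical(a$end, b$end)
}

new_track <- function(grid, value, kind, params = NULL) {
  out <- tibble(
    chrom = grid$chrom,
    start = grid$start,
    end = grid$end,
    value = as.numeric(value)
  )
  attr(out, "kind") <- kind
  if (!is.null(params)) attr(out, "params") <- params
  out
}

track_kind <- function(track) attr(track, "kind") %||% NA_character_

# distance between two 0-based half-open intervals (0 when they overlap)
interval_distance <- function(a_start, a_end, b_start, b_end) {
  pmax(b_start - a_end, a_start - b_end, 0L)
}

# derive a stage seed from a base seed, staying inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 113 + offset) %% 2147483587) + 1L
}

check_count <- function(x, arg, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", arg, min))
  }
  as.integer(x)
}

check_number <- function(x, arg, min = -Inf, max = Inf, strict_min = FALSE) {
  ok <- length(x) == 1 && is.finite(x) && x <= max &&
    (if (strict_min) x > min else x >= min)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s.", arg,
                  if (strict_min) ">" else ">=", min))
  }
  as.numeric(x)
}
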