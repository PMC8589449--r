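# Per-promoter TSS distribution statistics. The percentile rule is the
# inclusive one used throughout: the smallest position (in scanning order)
# whose cumulative count reaches q% of the row total. Applied uniformly to
# the 10th, 50th and 90th percentiles.

#' Percentile position of a 5'-end count row
#'
#' Returns the smallest offset, in scanning order, at which the cumulative
#' read count reaches `q`% of the row total — e.g. `q = 50` gives the
#' actual TSS containing the 50th percentile of the distribution (the
#' median TSS position).
#'
#' @param counts Non-negative counts over window offsets, upstream to
#'   downstream.
#' @param q Percent in (0, 100].
#' @param offsets Integer offsets labelling `counts`; defaults to
#'   `-250..` when `counts` has 401 elements, else `seq_along(counts) - 1`.
#' @return The offset (integer) holding the q-th percentile.
#' @export
#' @examples
#' percentile_position(c(0, 0, 5, 3, 2, 0), 50, offsets = 1:6)  # 3
percentile_position <- function(counts, q, offsets = NULL) {
  stopifnot(q > 0, q <= 100)
  offsets <- default_offsets(counts, offsets)
  total <- sum(counts)
  if (total <= 0) abort("percentile undefined for a zero-count row")
  cum <- cumsum(counts)
  offsets[which(cum >= q / 100 * total)[1]]
}

default_offsets <- function(counts, offsets) {
  if (!is.null(offsets)) {
    stopifnot(length(offsets) == length(counts))
    return(as.integer(offsets))
  }
  if (length(counts) == 401) seq.int(-250L, 150L)
  else seq_along(counts) - 1L
}

#' TSS spread of a count row
#'
#' The width of the middle 80% of the distribution: 90th-percentile
#' position minus 10th-percentile position, plus 1 nt.
#'
#' @inheritParams percentile_position
#' @return Spread in nt (positive integer).
#' @export
tss_spread <- function(counts, offsets = NULL) {
  percentile_position(counts, 90, offsets) -
    percentile_position(counts, 10, offsets) + 1L
}

#' Expression-spread-median metrics for every promoter
#'
#' Computes, per table row: expression (total window reads), the 10th/50th/
#' 90th-percentile positions and the TSS spread. Empty rows are emitted
#' with expression 0 and `NA` metrics. The same computation applies
#' unchanged to ChIP-exo 5'-binding matrices read with [read_cdt()].
#'
#' @param table A `tss_count_table`.
#' @return A `tss_metrics` tibble with columns `promoter_id`, `expression`,
#'   `p10_pos`, `median_pos`, `p90_pos`, `spread`.
#' @export
metrics_table <- function(table) {
  m <- count_matrix(table)
  offsets <- table_offsets(table)
  totals <- rowSums(m)
  stat <- function(q) {
    apply(m, 1, function(r) {
      if (sum(r) <= 0) NA_integer_ else percentile_position(r, q, offsets)
    })
  }
  out <- tibble(
    promoter_id = table$promoter_id,
    expression = as.integer(round(totals)),
    p10_pos = as.integer(stat(10)),
    median_pos = as.integer(stat(50)),
    p90_pos = as.integer(stat(90))
  )
  out$spread <- out$p90_pos - out$p10_pos + 1L
  class(out) <- unique(c("tss_metrics", class(out)))
  out
}

#' Mutant-versus-WT TSS shift and spread-change table
#'
#' Shift is the mutant median TSS position minus the WT median TSS
#' position in scanning-oriented coordinates, so positive means a
#' downstream shift; spread change is mutant spread minus WT spread
#' (negative = narrowing). Promoters lacking metrics on either side get
#' `NA` (no imputation).
#'
#' @param mutant_metrics,wt_metrics `tss_metrics` tibbles (typically from
#'   replicate-summed genotype tables).
#' @return A `tss_shifts` tibble with `promoter_id`, `shift`,
#'   `spread_change`.
#' @export
shift_table <- function(mutant_metrics, wt_metrics) {
  out <- dplyr::inner_join(
    dplyr::select(mutant_metrics, "promoter_id",
                  mut_median = "median_pos", mut_spread = "spread"),
    dplyr::select(wt_metrics, "promoter_id",
                  wt_median = "median_pos", wt_spread = "spread"),
    by = "promoter_id"
  ) |>
    dplyr::mutate(shift = .data$mut_median - .data$wt_median,
                  spread_change = .data$mut_spread - .data$wt_spread) |>
    dplyr::select("promoter_id", "shift", "spread_change")
  class(out) <- unique(c("tss_shifts", class(out)))
  out
}

#' Write expression-spread-median / shift tables as TSV
#'
#' @param x A `tss_metrics` or `tss_shifts` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
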