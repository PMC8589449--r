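# Promoter x offset count tables in scanning-oriented coordinates.
# Offsets run -upstream..+downstream (default -250..+150, 401 columns),
# increasing in the scanning (downstream) direction for both strands:
# genomic position = anchor + offset on '+', anchor - offset on '-'.

offset_cols <- function(table) setdiff(names(table), "promoter_id")

table_offsets <- function(table) as.integer(offset_cols(table))

count_matrix <- function(table) {
  m <- as.matrix(table[, offset_cols(table), drop = FALSE])
  rownames(m) <- table$promoter_id
  m
}

new_count_table <- function(promoter_ids, m, offsets, source_label = NULL,
                            class = "tss_count_table") {
  colnames(m) <- as.character(offsets)
  out <- dplyr::bind_cols(tibble(promoter_id = promoter_ids), as_tibble(m))
  attr(out, "source_label") <- source_label
  class(out) <- unique(c(class, "tss_table", class(out)))
  out
}

#' Build a strand-oriented promoter-window count table
#'
#' For every promoter, 5'-end counts are collected in a window spanning
#' `upstream` nt upstream to `downstream` nt downstream of the annotation
#' anchor (the previously annotated median TSS), oriented in the scanning
#' direction: offset o maps to genomic position `anchor + o` for a
#' plus-strand promoter and `anchor - o` for a minus-strand promoter.
#' Positions beyond a chromosome end simply contribute zero. With the
#' defaults the window is 401 nt wide (-250..+150).
#'
#' @param signal A `tss_signal` tibble (one library or a merged genotype).
#' @param promoters Promoter annotation tibble (see [read_promoters()]).
#' @param upstream,downstream Non-negative window extents in nt.
#' @param source_label Optional label describing the signal source.
#' @return A `tss_count_table`: a tibble whose first column is
#'   `promoter_id` (in annotation order) followed by one integer column per
#'   offset, named by the offset.
#' @export
build_count_table <- function(signal, promoters, upstream = 250,
                              downstream = 150, source_label = NULL) {
  stopifnot(upstream >= 0, downstream >= 0)
  promoters <- validate_promoters(promoters)
  signal <- as_stranded_signal(signal)
  offsets <- seq.int(-upstream, downstream)
  n <- nrow(promoters)
  m <- matrix(0L, nrow = n, ncol = length(offsets))
  if (nrow(signal) > 0 && n > 0) {
    cells <- promoters |>
      dplyr::select("promoter_id", "chrom", "strand", "anchor") |>
      dplyr::mutate(row = dplyr::row_number()) |>
      tidyr::crossing(offset = offsets) |>
      dplyr::mutate(pos = ifelse(.data$strand == "+",
                                 .data$anchor + .data$offset,
                                 .data$anchor - .data$offset)) |>
      dplyr::inner_join(signal, by = c("chrom", "strand", "pos"))
    if (nrow(cells) > 0) {
      m[cbind(cells$row, cells$offset + upstream + 1L)] <- cells$count
    }
  }
  new_count_table(promoters$promoter_id, m, offsets, source_label)
}

#' Filter promoters by mean wild-type expression
#'
#' Retains promoters whose mean per-WT-library window read total is at
#' least `min_mean_reads` (default 100 reads). Returns the retained
#' promoter ids so the same subset can be applied consistently to every
#' downstream table via [subset_table()].
#'
#' @param wt_tables A list of `tss_count_table`s, one per WT library, all
#'   sharing promoter order.
#' @param min_mean_reads Threshold on the mean row sum.
#' @return Character vector of retained promoter ids, in table order.
#' @export
filter_expressed <- function(wt_tables, min_mean_reads = 100) {
  if (is.data.frame(wt_tables)) wt_tables <- list(wt_tables)
  if (length(wt_tables) == 0) abort("filter_expressed() needs >= 1 WT table")
  ids <- wt_tables[[1]]$promoter_id
  for (t in wt_tables) {
    if (!identical(t$promoter_id, ids)) {
      abort("WT tables must share promoter order")
    }
  }
  totals <- vapply(wt_tables, function(t) rowSums(count_matrix(t)),
                   numeric(length(ids)))
  mean_reads <- rowMeans(matrix(totals, nrow = length(ids)))
  ids[mean_reads >= min_mean_reads]
}

#' Subset a promoter table to a set of ids, preserving order
#'
#' @param table A `tss_count_table` (or normalized/difference table).
#' @param ids Promoter ids to keep; row order follows `table`.
#' @return The subsetted table, same class.
#' @export
subset_table <- function(table, ids) {
  out <- table[table$promoter_id %in% ids, , drop = FALSE]
  attr(out, "source_label") <- attr(table, "source_label")
  out
}

#' Row-normalize a count table to relative TSS usage
#'
#' Each row is divided by its total so rows sum to 1. Rows with zero total
#' ("empty" promoters) are flagged by setting every cell to `NA`; they are
#' excluded from difference maps.
#'
#' @param table A `tss_count_table`.
#' @return A `tss_norm_table` tibble of per-position usage fractions.
#' @export
normalize_rows <- function(table) {
  m <- count_matrix(table)
  totals <- rowSums(m)
  norm <- m / totals
  norm[totals == 0, ] <- NA_real_
  new_count_table(table$promoter_id, norm, table_offsets(table),
                  attr(table, "source_label"), class = "tss_norm_table")
}

#' Mutant-minus-wild-type difference of normalized tables
#'
#' Element-wise `mutant - wt` of relative TSS usage; a row where either
#' side is empty is flagged missing (`NA`). Each defined row sums to 0.
#'
#' @param mutant,wt `tss_norm_table`s over the same promoters and offsets.
#' @return A `tss_diff_table` tibble of signed usage differences.
#' @export
diff_tables <- function(mutant, wt) {
  if (!identical(mutant$promoter_id, wt$promoter_id) ||
      !identical(table_offsets(mutant), table_offsets(wt))) {
    abort("mutant and WT tables must share promoters and offsets")
  }
  d <- count_matrix(mutant) - count_matrix(wt)
  lab <- paste0(attr(mutant, "source_label") %||% "mutant", " - ",
                attr(wt, "source_label") %||% "WT")
  new_count_table(mutant$promoter_id, d, table_offsets(mutant), lab,
                  class = "tss_diff_table")
}

#' Rank promoters by wild-type expression within class
#'
#' Stable descending sort of promoters by WT window read total, within
#' promoter class when `classes` is given — the row ordering used for
#' expression-ranked heatmaps.
#'
#' @param table A `tss_count_table` (used for promoter ids and order).
#' @param wt_totals Numeric WT row totals aligned with `table` rows.
#' @param classes Optional class label per row; sorting is within class,
#'   classes kept in first-appearance order.
#' @return Character vector of promoter ids in display order.
#' @export
order_by_wt_expression <- function(table, wt_totals, classes = NULL) {
  ids <- table$promoter_id
  stopifnot(length(wt_totals) == length(ids))
  if (is.null(classes)) classes <- rep("all", length(ids))
  cls <- factor(classes, levels = unique(classes))
  # order() is a stable sort, so ties keep input order
  ids[order(cls, -wt_totals)]
}

#' Write / read a promoter table as CSV
#'
#' First column `promoter_id`, then one column per window offset, headed by
#' the offset (default -250..150).
#'
#' @param table A promoter table (`tss_count_table` or kin).
#' @param path Output path (`.gz` allowed).
#' @return `path` invisibly for the writer; the table for the reader.
#' @export
write_count_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "promoter_id"
  x$promoter_id <- as.character(x$promoter_id)
  m <- as.matrix(x[, -1, drop = FALSE])
  new_count_table(x$promoter_id, m, as.integer(colnames(m)))
}

#' Read a CDT-format 5'-position matrix
#'
#' Tab-separated matrices with leading id column(s), as produced for
#' ChIP-exo 5'-boundary analyses; columns are window offsets. Non-numeric
#' leading columns beyond the first are dropped. The result is an ordinary
#' `tss_count_table`, so the same median/spread/shift machinery applies to
#' protein-binding 5' positions.
#'
#' @param path Path to the CDT/TSV matrix.
#' @param offsets Optional integer offsets for the data columns; defaults
#'   to the numeric column names, else -250..(ncol-251).
#' @return A `tss_count_table`.
#' @export
read_cdt <- function(path, offsets = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  numeric_col <- vapply(x, is.numeric, logical(1))
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, numeric_col, drop = FALSE])
  if (is.null(offsets)) {
    offsets <- suppressWarnings(as.integer(colnames(m)))
    if (anyNA(offsets)) offsets <- seq.int(-250, length.out = ncol(m))
  }
  new_count_table(ids, m, offsets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
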