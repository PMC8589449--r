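# Per-position 5' end signal: a tibble with columns chrom, strand, pos, count.
# Positions are 1-based single nucleotides; zero-count positions are never
# stored. bedGraph (0-based, half-open) is converted at the I/O boundary.

#' Construct or validate a stranded 5'-end signal
#'
#' A stranded signal is the package's sparse per-position representation of
#' 5' sequencing-read ends: one row per (chromosome, strand, position) that
#' carries at least one read. Positions are 1-based single nucleotides.
#'
#' @param x A data frame with columns `chrom`, `strand`, `pos`, `count`.
#' @param library_id Optional library identifier stored as an attribute.
#' @return A tibble of class `tss_signal` with one row per nonzero position,
#'   sorted by chromosome, strand and position.
#' @export
#' @examples
#' as_stranded_signal(
#'   data.frame(chrom = "chrI", strand = "+", pos = c(3, 3, 7), count = 1)
#' )
as_stranded_signal <- function(x, library_id = NULL) {
  x <- as_tibble(x)
  required <- c("chrom", "strand", "pos", "count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("signal is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (!all(x$strand %in% c("+", "-"))) {
      abort("signal strand must be '+' or '-'")
    }
    if (any(x$pos < 1) || any(x$pos != floor(x$pos))) {
      abort("signal positions must be 1-based positive integers")
    }
    if (any(x$count < 0)) abort("signal counts must be non-negative")
  }
  out <- x |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$chrom, .data$strand, .data$pos) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$strand, .data$pos)
  out$pos <- as.integer(out$pos)
  out$count <- as.integer(round(out$count))
  attr(out, "library_id") <- library_id
  class(out) <- unique(c("tss_signal", class(out)))
  out
}

empty_signal <- function(library_id = NULL) {
  as_stranded_signal(
    tibble(chrom = character(), strand = character(),
           pos = integer(), count = integer()),
    library_id = library_id
  )
}

#' Read a stranded bedGraph file into per-position 5'-end signal
#'
#' bedGraph intervals (0-based, half-open) are expanded to single 1-based
#' nucleotide positions; a run of length L with value v becomes L positions
#' each carrying count v. Zero-valued runs are dropped. Because TSS-seq
#' pileups are strand-split into one file per strand, the strand is supplied
#' by the caller, not read from the file.
#'
#' @param path Path to a 4-column bedGraph file (plain or gzip).
#' @param strand `"+"` or `"-"`; assigned to every position in the file.
#' @param library_id Optional library identifier.
#' @return A `tss_signal` tibble (see [as_stranded_signal()]).
#' @export
read_bedgraph <- function(path, strand, library_id = NULL) {
  stopifnot(strand %in% c("+", "-"))
  lines <- readLines(gzfile(path))
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_signal(library_id))
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_fields <- lengths(fields)
  bad <- which(n_fields != 4)
  if (length(bad) > 0) {
    abort(sprintf("bedGraph parse error at line %d: expected 4 columns, got %d",
                  bad[1], n_fields[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | is.na(value) | value != floor(value) |
                 value < 0 | start < 0 | end <= start)
  if (length(bad) > 0) {
    abort(sprintf("bedGraph parse error at line %d: '%s'",
                  bad[1], lines[bad[1]]))
  }
  keep <- value > 0
  if (!any(keep)) return(empty_signal(library_id))
  chrom <- m[keep, 1]
  start <- start[keep]; end <- end[keep]; value <- value[keep]
  width <- as.integer(end - start)
  # expand each half-open run [start, end) to 1-based points start+1 .. end
  pos <- sequence(width, from = as.integer(start + 1))
  as_stranded_signal(
    tibble(chrom = rep(chrom, width), strand = strand,
           pos = pos, count = rep(value, width)),
    library_id = library_id
  )
}

#' Write a stranded signal to a bedGraph file
#'
#' Adjacent positions with equal counts are run-length merged so that
#' `read_bedgraph(write_bedgraph(s))` round-trips exactly. Only the rows of
#' `signal` on `strand` are written, matching the two-file-per-library
#' convention. A path ending in `.gz` is gzip-compressed.
#'
#' @param signal A `tss_signal` tibble.
#' @param path Output path.
#' @param strand `"+"` or `"-"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(signal, path, strand) {
  stopifnot(strand %in% c("+", "-"))
  signal <- as_stranded_signal(signal)
  s <- signal |>
    dplyr::filter(.data$strand == .env$strand) |>
    dplyr::arrange(.data$chrom, .data$pos)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(s) == 0) {
    cat("", file = con)
    return(invisible(path))
  }
  # merge runs: same chrom, consecutive pos, equal count
  new_run <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                 s$pos[-1] != s$pos[-nrow(s)] + 1L |
                 s$count[-1] != s$count[-nrow(s)])
  run <- cumsum(new_run)
  runs <- s |>
    dplyr::mutate(run = run) |>
    dplyr::group_by(run) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$pos) - 1L, end = max(.data$pos),
                     value = dplyr::first(.data$count), .groups = "drop")
  writeLines(sprintf("%s\t%d\t%d\t%d", runs$chrom, runs$start,
                     runs$end, runs$value), con)
  invisible(path)
}

#' Collapse mapped-read intervals to 5'-end signal
#'
#' For a plus-strand read the 5' end is the first base of the interval
#' (1-based `start + 1`); for a minus-strand read it is the last base
#' (`end`). Counts accumulate per position.
#'
#' @param reads A data frame of read intervals with columns `chrom`,
#'   `start` (0-based inclusive), `end` (0-based exclusive), `strand`.
#' @param library_id Optional library identifier.
#' @return A `tss_signal` tibble.
#' @export
extract_five_prime_ends <- function(reads, library_id = NULL) {
  reads <- as_tibble(reads)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (nrow(reads) == 0) return(empty_signal(library_id))
  if (any(reads$start >= reads$end)) {
    abort("read intervals must satisfy start < end")
  }
  if (!all(reads$strand %in% c("+", "-"))) {
    abort("read strand must be '+' or '-'")
  }
  as_stranded_signal(
    reads |>
      dplyr::mutate(pos = ifelse(.data$strand == "+",
                                 .data$start + 1L, .data$end),
                    count = 1L) |>
      dplyr::select("chrom", "strand", "pos", "count"),
    library_id = library_id
  )
}

#' Read uniquely-mapped read intervals from a BED file
#'
#' Only chrom, start, end and strand (columns 1-3 and 6) are consumed.
#'
#' @param path Path to a BED6 file (plain or gzip).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_bed_reads <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  if (ncol(x) < 6) abort("BED file must have at least 6 columns")
  tibble(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
         end = as.integer(x[[3]]), strand = as.character(x[[6]]))
}

#' Read a promoter annotation table
#'
#' Tab-separated with header columns `promoter_id`, `chrom`, `strand`,
#' `anchor`, `class_label`. The anchor is the previously annotated median
#' TSS (1-based) on which the scanning-oriented promoter window is centred;
#' `class_label` carries the promoter class (e.g. Taf1-enriched/-depleted).
#' Row order is preserved and defines count-table row order.
#'
#' @param path Path to the annotation TSV (plain or gzip).
#' @return A tibble with one row per promoter, in file order.
#' @export
read_promoters <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         promoter_id = readr::col_character(),
                         chrom = readr::col_character(),
                         strand = readr::col_character(),
                         anchor = readr::col_integer(),
                         class_label = readr::col_character()
                       ))
  validate_promoters(x)
}

validate_promoters <- function(x) {
  x <- as_tibble(x)
  required <- c("promoter_id", "chrom", "strand", "anchor", "class_label")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("promoter annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(x$promoter_id)) {
    abort("duplicate promoter_id in annotation")
  }
  if (!all(x$strand %in% c("+", "-"))) {
    abort("promoter strand must be '+' or '-'")
  }
  if (any(x$anchor < 1)) abort("promoter anchor must be >= 1")
  x
}

#' Sum stranded signals position-wise
#'
#' Used to pool biological replicates into one combined library per
#' genotype before window construction and metrics.
#'
#' @param ... `tss_signal` tibbles, or a single list of them.
#' @param library_id Optional identifier for the merged signal.
#' @return A `tss_signal` tibble with position-wise summed counts.
#' @export
merge_signals <- function(..., library_id = NULL) {
  signals <- list(...)
  if (length(signals) == 1 && is.list(signals[[1]]) &&
      !is.data.frame(signals[[1]])) {
    signals <- signals[[1]]
  }
  if (length(signals) == 0) abort("merge_signals() needs at least one signal")
  as_stranded_signal(dplyr::bind_rows(signals), library_id = library_id)
}
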