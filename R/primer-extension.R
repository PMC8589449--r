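# Binned quantification of primer-extension lanes: per-lane signal is
# normalized to fractions over an ordered, non-overlapping bin scheme,
# replicates averaged within genotype, and the WT profile subtracted bin
# by bin. Offsets are relative to the translational start codon (upstream
# negative), the primer-extension convention.

#' Define a TSS bin scheme
#'
#' Bins are contiguous, non-overlapping, ordered upstream to downstream.
#'
#' @param bin_id Character or integer bin labels, upstream to downstream.
#' @param start_offset,end_offset Inclusive interval bounds per bin
#'   (start <= end, in window-offset units).
#' @return A `bin_scheme` tibble.
#' @export
bin_scheme <- function(bin_id, start_offset, end_offset) {
  stopifnot(length(bin_id) == length(start_offset),
            length(bin_id) == length(end_offset))
  if (length(bin_id) < 2) abort("a bin scheme needs >= 2 bins")
  if (any(start_offset > end_offset)) abort("bin start must be <= end")
  if (any(diff(start_offset) <= 0) ||
      any(start_offset[-1] <= end_offset[-length(end_offset)])) {
    abort("bins must be ordered upstream to downstream and non-overlapping")
  }
  out <- tibble(bin_id = as.character(bin_id),
                start_offset = as.integer(start_offset),
                end_offset = as.integer(end_offset))
  class(out) <- unique(c("bin_scheme", class(out)))
  out
}

#' Default six-bin scheme for the ADH1 promoter
#'
#' Six bins running upstream to downstream over the ADH1 TSS region, with
#' the two major TSSs — 37 nt (-37) and 27 nt (-27) upstream of the start
#' codon — falling in bins 3 and 5 respectively. Published boundaries are
#' drawn graphically rather than enumerated, so these coordinates are a
#' documented approximation (see the `approximate` attribute); supply
#' exact boundaries via [bin_scheme()] for other promoters.
#'
#' @return A `bin_scheme` tibble with an `approximate = TRUE` attribute.
#' @export
adh1_bins <- function() {
  out <- bin_scheme(
    bin_id = as.character(1:6),
    start_offset = c(-70L, -50L, -40L, -33L, -28L, -23L),
    end_offset   = c(-51L, -41L, -34L, -29L, -24L, -10L)
  )
  attr(out, "approximate") <- TRUE
  out
}

#' Normalize one lane's bin signal to fractions
#'
#' @param lane Non-negative numeric vector of per-bin raw signal.
#' @return Fractions summing to 1.
#' @export
normalize_lane <- function(lane) {
  lane <- as.numeric(lane)
  if (any(lane < 0)) abort("lane signal must be non-negative")
  total <- sum(lane)
  if (total <= 0) abort("cannot normalize a zero lane")
  lane / total
}

#' Mutant-minus-WT bin differences, averaged over replicates
#'
#' Each lane is normalized to fractions, lanes are averaged within
#' genotype, and the WT mean is subtracted from the mutant mean bin by
#' bin. Positive values in upstream bins mean the mutant shifts usage
#' upstream. The reported sd is taken across mutant replicates of
#' (replicate - WT mean). A warning is issued when a genotype has fewer
#' than 3 replicates.
#'
#' @param mutant_lanes,wt_lanes Matrices or data frames with one lane per
#'   row and one column per bin (same bin count on both sides).
#' @return A tibble with `bin_id`, `mutant_mean`, `wt_mean`, `diff`, `sd`.
#' @export
diff_bins <- function(mutant_lanes, wt_lanes) {
  mm <- lane_matrix(mutant_lanes)
  wm <- lane_matrix(wt_lanes)
  if (ncol(mm) != ncol(wm)) abort("mutant and WT lanes use different bin schemes")
  if (nrow(mm) < 3 || nrow(wm) < 3) {
    warn("fewer than 3 replicates in a genotype; sd will be unstable")
  }
  mn <- t(apply(mm, 1, normalize_lane))
  wn <- t(apply(wm, 1, normalize_lane))
  wt_mean <- colMeans(wn)
  mut_mean <- colMeans(mn)
  rep_diffs <- sweep(mn, 2, wt_mean)  # per mutant replicate, vs WT mean
  sds <- if (nrow(mn) > 1) apply(rep_diffs, 2, stats::sd) else rep(NA_real_, ncol(mn))
  tibble(bin_id = colnames(mm) %||% as.character(seq_len(ncol(mm))),
         mutant_mean = mut_mean, wt_mean = wt_mean,
         diff = mut_mean - wt_mean, sd = sds)
}

lane_matrix <- function(lanes) {
  if (is.data.frame(lanes)) {
    num <- vapply(lanes, is.numeric, logical(1))
    m <- as.matrix(lanes[, num, drop = FALSE])
  } else {
    m <- as.matrix(lanes)
    if (nrow(m) == 1 || ncol(m) == 1) m <- matrix(as.numeric(m), nrow = 1)
  }
  m
}

#' Summarize per-position signal into gel bins
#'
#' Bridges sequencing-derived (or simulated) per-offset 5'-end counts into
#' the bin space of a primer-extension gel. Positions outside every bin
#' are dropped with a warning.
#'
#' @param signal A data frame with columns `offset` and `count`, or a
#'   named numeric vector (names = offsets).
#' @param scheme A [bin_scheme()].
#' @return A tibble with `bin_id` and `signal` (per-bin sums).
#' @export
bin_from_positions <- function(signal, scheme) {
  if (!is.data.frame(signal)) {
    signal <- tibble(offset = as.integer(names(signal)),
                     count = as.numeric(signal))
  }
  stopifnot(all(c("offset", "count") %in% names(signal)))
  idx <- vapply(signal$offset, function(o) {
    hit <- which(scheme$start_offset <= o & o <= scheme$end_offset)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  dropped <- sum(signal$count[is.na(idx)])
  if (dropped > 0) {
    warn(sprintf("%g signal units fall outside all bins and were dropped",
                 dropped))
  }
  sums <- vapply(seq_len(nrow(scheme)), function(b) {
    sum(signal$count[!is.na(idx) & idx == b])
  }, numeric(1))
  tibble(bin_id = scheme$bin_id, signal = sums)
}

#' Read lane quantifications from CSV
#'
#' Expected columns: `lane_id`, `replicate`, `genotype`, then one numeric
#' column per bin (`bin1`..`binK` or the scheme's bin ids).
#'
#' @param path CSV path.
#' @return A tibble of lane quantifications.
#' @export
read_lanes <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("lane_id", "replicate", "genotype")
  if (!all(required %in% names(x))) {
    abort("lane table needs columns lane_id, replicate, genotype")
  }
  num <- vapply(x, is.numeric, logical(1))
  num[required] <- FALSE
  if (!any(num)) abort("lane table has no numeric bin columns")
  bad <- vapply(which(num), function(j) any(x[[j]] < 0, na.rm = TRUE), logical(1))
  if (any(bad)) abort("bin signal must be non-negative")
  x
}
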