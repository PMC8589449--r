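# Significance machinery for shift and spread tables: Wilcoxon signed-rank
# against zero for per-promoter shifts, and Kruskal-Wallis with Dunn's
# post-hoc z-tests (Bonferroni-adjusted) for spread distributions across
# genotypes. Dunn's test is computed directly from the pooled ranks with
# the standard tie correction.

#' Test whether per-promoter TSS shifts are centred on zero
#'
#' Two-sided Wilcoxon signed-rank test of the shift distribution against a
#' zero median. Missing shifts are dropped; at least 6 non-missing values
#' are required. If every shift is exactly zero the test is vacuous and
#' p = 1 is returned by convention.
#'
#' @param shifts Numeric vector of shifts (nt), or a `tss_shifts` tibble.
#' @return A `tss_shift_test` list with `p.value`, `statistic`, `n`
#'   (non-missing shifts) and `n_nonzero`.
#' @export
test_shifts_nonzero <- function(shifts) {
  if (is.data.frame(shifts)) shifts <- shifts$shift
  x <- shifts[!is.na(shifts)]
  if (length(x) < 6) abort("need at least 6 non-missing shifts")
  nz <- sum(x != 0)
  if (nz == 0) {
    out <- list(p.value = 1, statistic = NA_real_, n = length(x),
                n_nonzero = 0L)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, mu = 0,
                                              alternative = "two.sided"))
    out <- list(p.value = ht$p.value, statistic = unname(ht$statistic),
                n = length(x), n_nonzero = nz)
  }
  structure(out, class = "tss_shift_test")
}

#' @export
print.tss_shift_test <- function(x, ...) {
  cat("Wilcoxon signed-rank test: median shift vs 0\n")
  cat(sprintf("  n = %d (%d nonzero), V = %s, p = %.3g\n", x$n, x$n_nonzero,
              format(x$statistic), x$p.value))
  invisible(x)
}

#' Compare TSS spread distributions across genotypes
#'
#' Kruskal-Wallis omnibus test over all groups, followed by Dunn's
#' rank-based z-tests of each mutant against the reference (first) group,
#' with Bonferroni adjustment across the mutant comparisons. Dunn's
#' statistic uses the pooled-rank means with the usual tie correction.
#'
#' @param groups Named list of numeric vectors (spreads); the first
#'   element is the reference (WT) group. Each group needs >= 2 values.
#' @return A `tss_spread_test` list: `kw_p` (omnibus), `comparisons`
#'   tibble (`group`, `z`, `p`, `p_adj`), `reference`.
#' @export
test_spreads_differ <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(lengths(groups) < 2)) abort("every group needs >= 2 values")
  kw <- stats::kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ni <- lengths(groups)
  ref <- names(groups)[1]
  others <- names(groups)[-1]
  z <- vapply(others, function(m) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[ref]] + 1 / ni[[m]]))
    (rbar[[m]] - rbar[[ref]]) / se
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  comparisons <- tibble(group = others, z = unname(z), p = unname(p),
                        p_adj = stats::p.adjust(p, method = "bonferroni"))
  structure(list(kw_p = kw$p.value, kw_statistic = unname(kw$statistic),
                 comparisons = comparisons, reference = ref),
            class = "tss_spread_test")
}

#' @export
print.tss_spread_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis omnibus p = %.3g (reference: %s)\n",
              x$kw_p, x$reference))
  print(x$comparisons)
  invisible(x)
}

#' @method tidy tss_spread_test
#' @export
tidy.tss_spread_test <- function(x, ...) x$comparisons

#' @method glance tss_spread_test
#' @export
glance.tss_spread_test <- function(x, ...) {
  tibble(kw_statistic = x$kw_statistic, kw_p = x$kw_p,
         n_comparisons = nrow(x$comparisons))
}

#' @method glance tss_shift_test
#' @export
glance.tss_shift_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, n = x$n,
         n_nonzero = x$n_nonzero)
}
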