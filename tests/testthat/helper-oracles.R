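# Independent oracles and fixture builders shared across the suite.

# Random sparse stranded signal on a small genome.
random_signal <- function(n_pos = 50, chroms = c("chrA", "chrB"),
                          max_pos = 500, max_count = 20) {
  tibble::tibble(
    chrom = sample(chroms, n_pos, replace = TRUE),
    strand = sample(c("+", "-"), n_pos, replace = TRUE),
    pos = sample.int(max_pos, n_pos, replace = TRUE),
    count = sample.int(max_count, n_pos, replace = TRUE)
  ) |> as_stranded_signal()
}

# Brute-force percentile oracle: expand the row into the explicit multiset
# of read positions and scan cumulatively. Independent of the package's
# vectorized cumsum implementation.
oracle_percentile <- function(counts, q, offsets = seq_along(counts) - 1L) {
  reads <- rep(offsets, times = counts)
  stopifnot(length(reads) > 0)
  need <- q / 100 * length(reads)
  running <- 0
  for (o in offsets) {
    running <- running + sum(reads == o)
    if (running >= need) return(o)
  }
  stop("unreachable")
}

oracle_spread <- function(counts, offsets = seq_along(counts) - 1L) {
  oracle_percentile(counts, 90, offsets) -
    oracle_percentile(counts, 10, offsets) + 1L
}

# Exact two-sided signed-rank p-value by enumeration over all 2^n sign
# assignments (no zeros, no ties assumed). V = sum of ranks of positives.
oracle_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  stopifnot(n <= 15)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  # two-sided: mass at least as far from the null mean as observed
  mean(abs(v_all - mu) >= abs(v_obs - mu))
}

# Geometric row: P(k) proportional to (1-r) r^k over k = 0..kmax.
geometric_row <- function(r, kmax = 400) (1 - r) * r^(0:kmax)

# Closed-form percentile of the truncated geometric via CDF 1 - r^(k+1).
oracle_geom_percentile <- function(r, q, kmax = 400) {
  cdf <- (1 - r^(1:(kmax + 1))) / (1 - r^(kmax + 1))
  which(cdf >= q / 100)[1] - 1L
}

# Tiny promoter fixture on both strands.
toy_promoters <- function() {
  tibble::tibble(
    promoter_id = c("pA", "pB", "pC"),
    chrom = c("chrA", "chrA", "chrB"),
    strand = c("+", "-", "+"),
    anchor = c(1000L, 3000L, 700L),
    class_label = c("Taf1-enriched", "Taf1-depleted", "Taf1-enriched")
  )
}
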