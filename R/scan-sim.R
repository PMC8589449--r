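# "Shooting gallery" promoter-scanning simulator. A preinitiation complex
# assembles upstream and scans downstream; at each scan step k it attempts
# initiation at the current position with probability p_k (set by innate
# site strength and a global efficiency scalar), and otherwise survives the
# move to the next position with continuation probability c (geometric
# processivity loss), optionally capped at a hard maximum distance. A
# foray ends at initiation, drop-off, or the window end. N forays
# ("polymerase flux") yield a per-position 5'-end count distribution with
# flux depletion: successful upstream initiation removes polymerases that
# would otherwise reach downstream sites.

#' Specify a promoter-scanning model
#'
#' @param strengths Per-scan-step innate TSS strengths in \[0, 1\]; step 0
#'   is the assembly-proximal first scanned position. Length sets the
#'   window length.
#' @param efficiency Positive "rate of firing" scalar E; the per-step
#'   initiation probability is `1 - exp(-E * s)`.
#' @param continuation Per-step scanning survival probability c in (0, 1].
#'   The median scanning distance is `log(0.5)/log(c)` steps.
#' @param flux Number of scanning forays N (polymerases entering the
#'   window).
#' @param start_offset Window offset of scan step 0 (default -50: assembly
#'   50 nt upstream of the annotated median TSS).
#' @param max_distance Optional hard processivity cap: scanning never
#'   proceeds past this step.
#' @param seed Optional RNG seed for [simulate_scan()].
#' @return A `scan_model` list.
#' @export
scan_model <- function(strengths, efficiency = 1,
                       continuation = 0.5^(1 / 60), flux = 1e5,
                       start_offset = -50L, max_distance = NULL,
                       seed = NULL) {
  strengths <- as.numeric(strengths)
  if (length(strengths) < 1 || any(strengths < 0) || any(strengths > 1)) {
    abort("strengths must lie in [0, 1]")
  }
  if (efficiency <= 0) abort("efficiency must be > 0")
  if (continuation <= 0 || continuation > 1) {
    abort("continuation must be in (0, 1]")
  }
  if (flux < 1) abort("flux must be >= 1")
  structure(list(strengths = strengths, efficiency = efficiency,
                 continuation = continuation, flux = as.integer(round(flux)),
                 start_offset = as.integer(start_offset),
                 max_distance = max_distance, seed = seed),
            class = "scan_model")
}

#' @export
print.scan_model <- function(x, ...) {
  cat(sprintf(
    "scan_model: %d steps from offset %d; E = %g, c = %.5f (median distance %.0f nt), N = %d\n",
    length(x$strengths), x$start_offset, x$efficiency, x$continuation,
    if (x$continuation < 1) log(0.5) / log(x$continuation) else Inf, x$flux))
  invisible(x)
}

#' Per-position initiation probability
#'
#' Combines innate target strength with the firing-rate scalar as
#' `p = 1 - exp(-efficiency * strength)`: smooth, bounded in \[0, 1),
#' strictly increasing in both arguments, and approximately
#' `efficiency * strength` when both are small.
#'
#' @param strength Innate site strength(s) in \[0, 1\].
#' @param efficiency Positive firing-rate scalar.
#' @return Initiation probability/ies in \[0, 1).
#' @export
initiation_prob <- function(strength, efficiency) {
  stopifnot(all(strength >= 0), all(strength <= 1), efficiency > 0)
  1 - exp(-efficiency * strength)
}

# per-foray outcome probabilities over steps 0..K-1 (and implicit
# no-product remainder): q_k = c^k p_k prod_{j<k}(1 - p_j)
foray_probs <- function(model) {
  p <- initiation_prob(model$strengths, model$efficiency)
  K <- length(p)
  k <- seq_len(K) - 1
  q <- model$continuation^k * p * cumprod(c(1, 1 - p))[seq_len(K)]
  if (!is.null(model$max_distance)) {
    q[k > model$max_distance] <- 0
  }
  q
}

#' Closed-form expected 5'-end count distribution
#'
#' The expected count at scan step k is
#' `N * c^k * p_k * prod_(j<k) (1 - p_j)`: flux N, geometric survival to
#' step k, failure to initiate anywhere upstream, initiation at k. Steps
#' past `max_distance` get 0.
#'
#' @param model A [scan_model()].
#' @return A tibble with `step`, `offset` and `expected` columns.
#' @export
expected_distribution <- function(model) {
  q <- foray_probs(model)
  tibble(step = seq_along(q) - 1L,
         offset = model$start_offset + seq_along(q) - 1L,
         expected = model$flux * q)
}

#' Simulate one promoter's scanning forays
#'
#' Draws `flux` independent forays from the model. Each foray's outcome
#' (initiation at step k, or no product) is categorical with the
#' closed-form foray probabilities, so the joint counts are sampled with
#' one multinomial draw — distribution-identical to walking every foray
#' step by step, and fast at deep flux.
#'
#' @param model A [scan_model()]; its `seed`, when set, makes the draw
#'   reproducible without touching the session RNG state.
#' @return A `scan_outcome` list: `counts` tibble (`step`, `offset`,
#'   `count`, `expected`), `n_no_product`, `flux`.
#' @export
simulate_scan <- function(model) {
  q <- foray_probs(model)
  draw <- function() {
    as.integer(stats::rmultinom(1, size = model$flux,
                                prob = c(q, 1 - sum(q))))
  }
  x <- if (!is.null(model$seed)) withr::with_seed(model$seed, draw()) else draw()
  K <- length(q)
  structure(list(
    counts = tibble(step = seq_len(K) - 1L,
                    offset = model$start_offset + seq_len(K) - 1L,
                    count = x[seq_len(K)],
                    expected = model$flux * q),
    n_no_product = x[K + 1L],
    flux = model$flux
  ), class = "scan_outcome")
}

#' @export
print.scan_outcome <- function(x, ...) {
  initiated <- sum(x$counts$count)
  cat(sprintf("scan_outcome: %d/%d forays initiated (%d no product)\n",
              initiated, x$flux, x$n_no_product))
  invisible(x)
}

#' Random innate strength profiles for synthetic promoters
#'
#' Emulates a yeast scanning promoter: a modest number of usable TSSs
#' scattered through the scanning window, with the first positions after
#' assembly blocked (initiation very close to the assembly point is not
#' observed). Strengths are weak individually so that distributions are
#' shaped by flux depletion and processivity, not by a single dominant
#' site.
#'
#' @param n_steps Scanning-window length in steps.
#' @param n_sites Range (min, max) of TSS-site counts per promoter.
#' @param site_steps Range of steps (inclusive) where sites may fall;
#'   default leaves steps 0..10 blocked.
#' @param strength_range Uniform range of per-site strengths.
#' @return Numeric strength vector of length `n_steps`.
#' @export
random_strengths <- function(n_steps = 201, n_sites = c(40, 55),
                             site_steps = c(11, n_steps - 1),
                             strength_range = c(0.01, 0.08)) {
  s <- numeric(n_steps)
  k <- if (n_sites[1] == n_sites[2]) n_sites[1] else
    sample(seq.int(n_sites[1], n_sites[2]), 1)
  pos <- sample(seq.int(site_steps[1], site_steps[2]), k)
  s[pos + 1] <- stats::runif(k, strength_range[1], strength_range[2])
  s
}

#' Named strength presets
#'
#' `"uniform"`: equal weak strength at every allowed step;
#' `"single-site"`: one strong site mid-window; `"adh1-like"`: two major
#' sites 10 nt apart over a weak background, mimicking a two-isoform
#' promoter.
#'
#' @param name Preset name.
#' @param n_steps Window length in steps.
#' @return Numeric strength vector.
#' @export
preset_strengths <- function(name = c("uniform", "single-site", "adh1-like"),
                             n_steps = 201) {
  name <- match.arg(name)
  s <- numeric(n_steps)
  allowed <- seq.int(12, n_steps)  # steps 11..n_steps-1, 1-based index
  switch(name,
    "uniform" = { s[allowed] <- 0.05; s },
    "single-site" = { s[round(n_steps / 2)] <- 0.9; s },
    "adh1-like" = {
      s[allowed] <- 0.005
      mid <- round(n_steps / 2)
      s[mid] <- 0.5; s[mid + 10] <- 0.5
      s
    })
}

#' Genotype presets: the simulator's study conditions
#'
#' Multipliers applied to the wild-type model. Efficiency alleles scale
#' the firing rate E four-fold; processivity alleles quadruple or quarter
#' the characteristic scanning distance (continuation `c^(1/4)` or
#' `c^4`).
#'
#' @return A tibble with `genotype`, `efficiency_mult`, `continuation_exp`.
#' @export
genotype_presets <- function() {
  tibble(
    genotype = c("wt", "efficiency-up", "efficiency-down",
                 "processivity-up", "processivity-down"),
    efficiency_mult = c(1, 4, 0.25, 1, 1),
    continuation_exp = c(1, 1, 1, 1 / 4, 4)
  )
}

apply_genotype <- function(model, genotype) {
  presets <- genotype_presets()
  row <- presets[presets$genotype == genotype, ]
  if (nrow(row) == 0) {
    abort(paste0("unknown genotype preset: ", genotype))
  }
  model$efficiency <- model$efficiency * row$efficiency_mult
  model$continuation <- model$continuation^row$continuation_exp
  model
}

#' Build a synthetic promoter set with per-promoter scanning models
#'
#' Places `n` non-overlapping promoters on a synthetic chromosome,
#' alternating strand and promoter class, each with its own random
#' strength profile. The annotation anchor plays the role of the
#' "previously annotated median TSS"; scanning starts `|start_offset|` nt
#' upstream of it.
#'
#' @param n Number of promoters.
#' @param seed RNG seed for the strength profiles.
#' @param n_steps,start_offset Scanning geometry (see [scan_model()]).
#' @param spacing Distance between consecutive anchors (must exceed the
#'   window; overlapping synthetic promoters are rejected).
#' @param ... Passed to [random_strengths()].
#' @return A list with `promoters` (annotation tibble) and `strengths`
#'   (named list of strength vectors).
#' @export
synthetic_promoters <- function(n, seed = 1, n_steps = 201,
                                start_offset = -50L, spacing = 1000L, ...) {
  if (spacing <= n_steps + abs(start_offset) + 250) {
    abort("promoter spacing too small: windows would overlap")
  }
  promoters <- tibble(
    promoter_id = sprintf("prom%03d", seq_len(n)),
    chrom = "chrS1",
    strand = rep(c("+", "-"), length.out = n),
    anchor = 2000L + spacing * (seq_len(n) - 1L),
    class_label = rep(c("Taf1-enriched", "Taf1-depleted"), length.out = n)
  )
  strengths <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) random_strengths(n_steps = n_steps, ...))
  })
  names(strengths) <- promoters$promoter_id
  list(promoters = promoters, strengths = strengths)
}

#' Simulate a sequencing library over a promoter set
#'
#' Runs one scanning simulation per promoter and maps the initiation
#' counts onto genomic coordinates (offset o at anchor + o on '+', anchor
#' - o on '-'), yielding a stranded 5'-end signal directly consumable by
#' [build_count_table()]. Per-promoter sub-seeds are derived from `seed`
#' so replicate libraries are reproducible.
#'
#' @param promoter_set Output of [synthetic_promoters()].
#' @param genotype One of [genotype_presets()]'s names.
#' @param flux Forays per promoter (sequencing depth knob).
#' @param depth_factor Multiplier on `flux` (> 0).
#' @param seed Integer seed for the library.
#' @param efficiency,continuation,start_offset Wild-type baseline
#'   parameters (see [scan_model()]).
#' @param library_id Optional label; defaults to the genotype.
#' @return A `tss_signal` tibble.
#' @export
emit_library <- function(promoter_set, genotype = "wt", flux = 1e5,
                         depth_factor = 1, seed = 1, efficiency = 1,
                         continuation = 0.5^(1 / 60), start_offset = -50L,
                         library_id = NULL) {
  if (depth_factor <= 0) abort("depth_factor must be > 0")
  promoters <- validate_promoters(promoter_set$promoters)
  strengths <- promoter_set$strengths
  rows <- purrr::map(seq_len(nrow(promoters)), function(i) {
    pr <- promoters[i, ]
    model <- scan_model(strengths[[pr$promoter_id]],
                        efficiency = efficiency,
                        continuation = continuation,
                        flux = round(flux * depth_factor),
                        start_offset = start_offset,
                        seed = (seed * 10007 + i) %% 2147483647)
    model <- apply_genotype(model, genotype)
    out <- simulate_scan(model)$counts |>
      dplyr::filter(.data$count > 0)
    if (nrow(out) == 0) return(NULL)
    tibble(chrom = pr$chrom, strand = pr$strand,
           pos = if (pr$strand == "+") pr$anchor + out$offset
                 else pr$anchor - out$offset,
           count = out$count)
  })
  as_stranded_signal(dplyr::bind_rows(rows),
                     library_id = library_id %||% genotype)
}

#' Write a simulated library as a stranded bedGraph pair + annotation
#'
#' @param signal A `tss_signal` (e.g. from [emit_library()]).
#' @param promoters Promoter annotation tibble.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three written paths, invisibly.
#' @export
write_library <- function(signal, promoters, dir, prefix = "library") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    plus = file.path(dir, paste0(prefix, "_plus.bedgraph")),
    minus = file.path(dir, paste0(prefix, "_minus.bedgraph")),
    promoters = file.path(dir, paste0(prefix, "_promoters.tsv"))
  )
  write_bedgraph(signal, paths["plus"], "+")
  write_bedgraph(signal, paths["minus"], "-")
  readr::write_tsv(promoters, paths["promoters"], progress = FALSE)
  invisible(paths)
}
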