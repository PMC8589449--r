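---
title: "Promoter-scanning TSS metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-scanning TSS metrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanseq)
library(dplyr)
```

# The problem

In *Saccharomyces cerevisiae* and related yeasts, transcription initiation
proceeds by promoter scanning: the preinitiation complex (PIC) assembles at
a core promoter and then inspects successive downstream positions, so one
promoter produces 5′ ends at many transcription start sites (TSSs).
TSS-seq reads out this distribution as per-position 5′-end counts.
`scanseq` provides the downstream half of such an experiment: strand-aware
promoter-window count tables, a small set of distribution statistics
(expression, percentile positions, median, spread), mutant-versus-wild-type
shift and spread-change tables with significance tests, replicate QC, and a
stochastic scanning simulator whose parameters are known by construction,
so every stage can be verified end to end without sequencing data.

# Coordinates

All internal analysis happens in **scanning-oriented window offsets**. A
promoter is annotated by an anchor (its previously annotated median TSS);
offset $o$ maps to genomic position $\mathrm{anchor} + o$ on a plus-strand
promoter and $\mathrm{anchor} - o$ on a minus-strand promoter. Negative
offsets are upstream and positive offsets downstream *in the direction of
scanning* for both strands, so every statistic below is a polarity
statement about scanning. The default window spans 250 nt upstream to
150 nt downstream of the anchor — 401 positions. Genomic coordinates exist
only at the I/O boundary: bedGraph intervals (0-based, half-open) are
expanded to 1-based single nucleotides on read, and zero-count positions
are never stored.

# Distribution statistics

For one promoter row with counts $x_o$ over offsets and total
$T = \sum_o x_o$:

* **expression** is $T$;
* the **q-th percentile position** is the smallest offset $o$ (in scanning
  order) with $\sum_{o' \le o} x_{o'} \ge \frac{q}{100} T$ — the actual
  TSS containing that percentile of the read distribution;
* the **median TSS position** is the 50th percentile position;
* the **spread** is $P_{90} - P_{10} + 1$ nt, the width of the middle 80%
  of the distribution;
* the **shift** of a mutant at one promoter is its median position minus
  the wild-type median position (positive = downstream), and the **spread
  change** is the analogous spread difference (negative = narrowing).

One inclusive percentile rule is applied uniformly at q = 10, 50 and 90;
it resolves ties automatically, and the rule is recorded in the pipeline
manifest. These operations are deliberately generic: a ChIP-exo
401-column 5′-boundary matrix read with `read_cdt()` goes through exactly
the same code path to give median protein-binding positions.

Two useful exact properties follow from the inclusive rule and are
enforced by property tests: percentile positions are monotone in $q$ and
invariant to scaling a row by any positive integer; and for rows with odd
total, mirroring the row negates the median about the window midpoint and
preserves the spread exactly (for even totals the rule picks the lower of
two medians, so mirror symmetry can be off by the tie gap — one reason the
suite pins the odd case).

# Filtering, normalization, differences

Promoters are kept when their mean window total across the designated
wild-type libraries is at least `min_mean_reads` (default 100 reads); the
retained id set is applied to every downstream table. Rows are normalized
to relative usage (rows sum to 1; zero rows are flagged empty rather than
divided), and difference maps are element-wise mutant minus wild type, so
each defined difference row sums to zero. The wild-type reference for
differences and shifts is the position-wise sum of all designated WT
libraries; shifts are computed between replicate-summed genotype tables,
not per replicate pair. Promoters missing from either side are dropped,
never imputed — except in the shift-profile PCA, where a missing shift is
imputed as 0 nt on the argument that a promoter with no measurable shift
contributes no signal to the mutant's profile.

# Statistical tests

Per-mutant shift distributions are tested against a zero median with a
two-sided Wilcoxon signed-rank test (`stats::wilcox.test`; exact for
small zero- and tie-free samples, normal approximation otherwise; all-zero
input returns p = 1 by convention). Spread distributions across genotypes
get a Kruskal–Wallis omnibus test followed by Dunn's rank-based z-tests of
each mutant against the reference group. Dunn's statistic is computed
directly from the pooled ranks with the standard tie correction
$\sum_t (t^3 - t) / [12(N-1)]$, because no installed package provides it;
the adjustment across mutant comparisons is fixed to Bonferroni, the
classic choice for Dunn's procedure. The test suite validates the
signed-rank p-values against a full enumeration over sign patterns at
n = 10 and the Dunn z-statistics against hand-computed tie-corrected
cases.

# Replicate QC

Pairwise library correlation restricts to genome positions with at least
`min_count` reads (default 3) in *both* libraries, then takes Pearson r of
the log2 counts. The filter guarantees positivity, so no pseudocount is
added — filter first, then log. Positions are pooled across strands into
one vector pair; with fewer than three qualifying shared positions the
correlation is reported as missing, not zero. The correlation matrix is
clustered under Euclidean distance with average linkage (the distance
metric follows the field's convention; the linkage is this package's
recorded choice), and
the tree is also exported as a Newick string. Replicate acceptance
(conventionally r > 0.85 plus mutual nearest-neighbour leaves) is left to
the caller: the package reports both r and leaf adjacency rather than
hard-coding a rule.

# The scanning simulator

The generator implements a shooting-gallery picture of scanning. Each of
$N$ polymerase forays starts at scan step 0 (offset `start_offset`,
default −50) and proceeds downstream. At step $k$ it initiates with
probability $p_k$ and otherwise survives the move to step $k+1$ with
continuation probability $c$; a foray ends at initiation, drop-off, the
optional hard cap `max_distance`, or the window end. The expected count at
step $k$ is

$$\mu_k = N \, c^{k} \, p_k \prod_{j<k} (1 - p_j),$$

which couples three effects: geometric processivity loss ($c^k$), flux
depletion by upstream initiation (the product term), and per-position
efficiency. The per-position initiation probability combines innate site
strength $s_k \in [0,1]$ with a global firing-rate scalar $E$ as
$p_k = 1 - e^{-E s_k}$ — smooth, bounded, monotone in both arguments, and
$\approx E s_k$ when small. The form is a modelling choice; any monotone
bounded alternative would preserve the qualitative predictions.

Because forays are i.i.d., the joint outcome counts are multinomial over
(steps, no-product); `simulate_scan()` therefore draws one multinomial
sample rather than walking each foray, which is distribution-identical
and fast at deep flux. Seeded draws restore the session RNG state.
Conservation (counts + no-product = N) holds exactly on every run.

Three closed-form consequences, all enforced as tests against
`expected_distribution()`:

* raising $E$ at fixed $c$ moves the normalized median upstream and
  shrinks the spread (upstream sites fire more, flux depletes faster);
* raising $c$ at fixed $E$ moves the median downstream and widens the
  spread;
* lowering $c$ rescales $\mu_k$ by $(c_1/c_2)^k$ — expected counts at
  step 0 are untouched while downstream counts shrink multiplicatively,
  so the *normalized* distribution gains upstream usage without any
  upstream site becoming more active. This is the truncation-not-
  activation signature that distinguishes processivity defects from
  efficiency gains.

## Default study conditions

The generator's defaults describe a scanning-limited yeast promoter and
were fixed from the closed-form analysis before any simulation-based test
was written:

* window of 201 scan steps mapping to offsets −50…+150 (PIC assembly
  50 nt upstream of the annotated median TSS);
* the first 10 steps carry zero strength — initiation too close to the
  assembly point is not observed, and the upstream constraint needs no
  separate mechanism;
* 40–55 TSS sites per promoter, uniformly placed over the remaining
  steps, with strengths drawn from U(0.01, 0.08): individually weak sites
  so that distributions are shaped by flux and processivity rather than a
  single dominant site;
* wild-type efficiency $E = 1$ and continuation $c = 0.5^{1/60}$, i.e. a
  median scanning distance of 60 bp, the same order as single-molecule
  estimates of PIC scanning processivity;
* strong-allele genotype presets: efficiency ×4 or ×0.25, continuation
  $c^{1/4}$ or $c^4$ (quadrupling or quartering the characteristic
  scanning distance);
* flux $N = 10^5$ forays per promoter per library for analysis-scale
  runs.

Acceptance-scale runs use 200 promoters at this flux; unit tests use
6–50 promoters at $10^3$–$10^4$ forays. These sizes are the package's
own choices: large enough that sampling noise in an integer median is
well below the preset effect sizes (analytically ≥2 nt at essentially
every promoter), small enough to run interactively.

## What the generator does and does not emulate

It emulates: one scanning window per promoter; upstream-to-downstream
polarity on both strands; per-position initiation scaled by efficiency;
geometric per-step processivity with an optional hard cap; finite flux
with depletion by upstream initiation; multinomial sampling noise; and
replicate libraries via derived sub-seeds. It does not emulate mappability
artifacts, sequence-dependent library biases, overlapping or bidirectional
promoters, nucleosome or chromatin structure, scanning-rate effects
distinct from processivity, or re-initiation after a successful start
(a foray terminates at initiation; the possibility that scanning continues
after initiation is noted but not modelled). Passing tests on synthetic
data therefore validate the *pipeline arithmetic and the model's internal
logic*, not the biological fidelity of any particular dataset.

# Primer-extension bins

Gel lanes quantified in external imaging software enter as per-bin numeric
tables. Lanes are normalized to fractions, averaged within genotype, and
the wild-type mean is subtracted bin by bin; the reported sd is taken
across mutant replicates of (replicate − WT mean), a conservative reading
of "mean ± sd over ≥3 replicates". The shipped ADH1 scheme places the two
major TSSs (−37 and −27 relative to the start codon) in bins 3 and 5; the
published boundaries are drawn graphically rather than enumerated, so the
scheme carries an `approximate = TRUE` attribute and users should supply
exact boundaries where they have them. `bin_from_positions()` bridges
sequencing-derived or simulated per-offset counts into the same bin space.

# Orchestration

This is an R-native analysis package, so the orchestration layer is a
function, not a shell tool: `run_pipeline()` takes a config (R list or
YAML path), validates every referenced path up front, runs the stages in
order, and writes count tables, metrics, shift tables, difference maps,
the correlation matrix and tree, PCA scores, and a `manifest.json`
recording parameters and package version — enough to re-execute the
identical run. `simulate_dataset()` wraps the generator the same way.
Outputs are deterministic given (inputs, config, seed); the test suite
asserts byte-identical reruns.

# Numerical and degenerate-input choices

* Zero-sum rows: flagged (NA), excluded from difference maps and shift
  tables; never silently dropped from count tables.
* Chromosome-end truncation: window cells beyond a chromosome simply read
  zero rather than erroring, since synthetic chromosomes may be short.
* Overlapping promoter windows each receive the shared signal
  independently; only the synthetic generator rejects overlap (it must
  know the ground truth per window).
* bedGraph writing run-length merges adjacent equal counts; reading
  re-expands, so round-trips are exact.
* `wilcox.test` zero handling: shifts equal to zero are dropped by the
  signed-rank procedure; the all-zero case is short-circuited to p = 1.
* Sub-seeds for per-promoter simulation are derived as
  `(seed * 10007 + i) mod (2^31 - 1)` in double arithmetic to stay inside
  R's integer range.

# Known limitations

The expression filter takes the mean over WT libraries only, as specified;
per-mutant coverage filters are not applied. Confidence intervals on
per-promoter medians are not estimated. The heatmap and PCA plots are
plain `ggplot2` renderings, not publication graphics. Whether heatmap row
ordering by WT expression should precede or follow filtering is not
externally fixed; this package orders after filtering.
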