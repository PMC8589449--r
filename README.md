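# scanseq

Downstream analysis of TSS-seq for organisms that initiate transcription
by **promoter scanning**, plus a stochastic scanning simulator for
verifying the whole pipeline against known ground truth.

In scanning initiation (budding yeast being the canonical case), the
preinitiation complex assembles at a core promoter and inspects successive
downstream positions, so each promoter produces RNA 5′ ends at many
transcription start sites (TSSs). Mutations in the Pol II active site or
in the TFIIH translocase change *where* within a promoter initiation
happens, and the readout is a change in the shape of the per-promoter
5′-end distribution. `scanseq` is for researchers who have stranded
per-position 5′-end counts (bedGraph) or mapped-read intervals (BED) and
want the standard battery of scanning-oriented promoter statistics.

## What it computes

For each promoter, 5′-end counts are collected in a strand-oriented
window (default 250 nt upstream to 150 nt downstream of the annotated
median TSS — 401 positions, downstream-positive for both strands). For a
row with counts $x_o$ and total $T$:

- **expression** $= T$;
- **percentile position** $P_q = \min\{o : \sum_{o' \le o} x_{o'} \ge \tfrac{q}{100}T\}$,
  with the **median TSS position** $= P_{50}$;
- **TSS spread** $= P_{90} - P_{10} + 1$ nt (width of the middle 80%);
- **TSS shift** $=$ mutant median $-$ WT median (positive = downstream);
  **spread change** $=$ mutant spread $-$ WT spread (negative = narrowing).

Around these: mean-WT-expression filtering, row normalization and
mutant-minus-WT difference maps, Wilcoxon signed-rank tests of shifts,
Kruskal–Wallis + Dunn tests of spreads, pairwise library correlation with
hierarchical clustering, PCA of per-promoter shift profiles, and binned
primer-extension lane quantification. The same median/spread machinery
applies unchanged to ChIP-exo 5′-boundary matrices (`read_cdt()`).

The simulator draws $N$ scanning forays per promoter; a foray initiates at
scan step $k$ with probability $p_k = 1 - e^{-E s_k}$ (innate strength
$s_k$, firing-rate scalar $E$) and otherwise survives the next step with
continuation probability $c$, giving expected counts
$\mu_k = N c^k p_k \prod_{j<k}(1-p_j)$. Raising $E$ shifts distributions
upstream and narrows them; lowering $c$ truncates downstream usage while
leaving step-0 expectations exactly unchanged. Closed-form expectations
(`expected_distribution()`) back every stochastic test.

## Worked example

Simulate a wild type and a processivity-deficient mutant over 50
promoters, then measure shifts:

```r
library(scanseq)

pset <- synthetic_promoters(50, seed = 1)
wt   <- emit_library(pset, "wt",                flux = 1e5, seed = 2)
lof  <- emit_library(pset, "processivity-down", flux = 1e5, seed = 3)

ct_wt  <- build_count_table(wt,  pset$promoters, source_label = "WT")
ct_lof <- build_count_table(lof, pset$promoters, source_label = "ssl2-like LOF")

keep   <- filter_expressed(list(ct_wt))      # mean >= 100 reads per WT library
m_wt   <- metrics_table(subset_table(ct_wt,  keep))
m_lof  <- metrics_table(subset_table(ct_lof, keep))
shifts <- shift_table(m_lof, m_wt)

head(m_wt, 3)
#> # A tibble: 3 × 6
#>   promoter_id expression p10_pos median_pos p90_pos spread
#>   <chr>            <int>   <int>      <int>   <int>  <int>
#> 1 prom001          42659     -33         -6      49     83
#> 2 prom002          42460     -20          0      59     80
#> 3 prom003          40175     -13         -3      60     74

head(shifts, 3)
#> # A tibble: 3 × 3
#>   promoter_id shift spread_change
#>   <chr>       <int>         <int>
#> 1 prom001       -14           -47
#> 2 prom002       -11           -30
#> 3 prom003        -6           -50

test_shifts_nonzero(shifts)
#> Wilcoxon signed-rank test: median shift vs 0
#>   n = 50 (50 nonzero), V = 0, p = 7.65e-10
```

Every promoter shifts upstream (negative, median −16.5 nt) and narrows —
the truncation signature of reduced scanning processivity: downstream
positions lose signal multiplicatively while upstream sites are not
activated, so relative upstream usage rises. Two independent WT replicate
libraries at this depth correlate at r ≈ 0.997
(`correlate_pair(wt, emit_library(pset, "wt", flux = 1e5, seed = 9))`).

`run_pipeline()` packages these stages (plus difference maps, correlation
clustering and PCA) behind a single YAML/list config and writes a
manifest; `simulate_dataset()` writes ready-to-analyse bedGraph pairs.
See the vignette in `vignettes/promoter-scanning.Rmd` for the model,
parameter meanings and design choices.

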