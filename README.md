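# cernascope

Concordant-dysregulation analysis of circRNA–miRNA–mRNA (ceRNA) regulatory
networks in two-group expression studies.

## The problem

Circular RNAs carry miRNA response elements and can sequester ("sponge")
miRNAs. Because sponging changes miRNA *availability* rather than miRNA
*abundance*, a dysregulated circRNA is predicted to shift its indirect mRNA
targets — reached through a bridging miRNA — in the **same** direction as
itself, while the miRNA layer stays flat. `cernascope` is for transcriptomics
researchers who want to test exactly that on a features × samples intensity
study (typically microarray, n as small as 4 vs 4 per group) across three
RNA layers.

The pipeline:

1. **Differential expression** — a feature is dysregulated when fold change
   ≥ 1.5 (or ≤ 1/1.5) *and* the exact two-sided Mann–Whitney p ≤ 0.05. At
   4 vs 4 the test is computed by complete enumeration of all 70 rank
   assignments (smallest attainable p = 2/70 ≈ 0.029), so a call requires
   complete group separation. BH FDR is reported, not selected on.
2. **Target-map composition** — circRNA→miRNA and miRNA→mRNA edge lists are
   joined into circRNA→mRNA reachability, one row per distinct bridging
   miRNA.
3. **Concordance statistics** — 2×2 tables of *targeted* × *relevantly
   dysregulated* (same direction for the sponge relation, opposite for
   direct miRNA targets), with odds ratio OR = ad/bc, Woolf 95% CI
   exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d)), Pearson chi-square p, flagged
   Haldane–Anscombe handling of zero cells, and a miRNA-adjusted logistic OR
   (Firth fallback under separation).
4. **Network construction** — regulatory triples (circRNA, miRNA, mRNA) with
   circRNA and mRNA dysregulated in the same direction; degree summaries;
   Cytoscape-ready SIF/GraphML/attribute export.
5. **Enrichment** — fold enrichment (k/n)/(K/N) with one-sided
   hypergeometric p and BH FDR, top terms ranked by fold enrichment.
6. **Synthetic data** — a generator that plants circRNA effects and
   propagates them through the maps with configurable penetrance, leaving
   miRNAs untouched, with a machine-readable truth record.

## Worked example

Simulate a scaled two-group study (200 circRNAs, 50 miRNAs, 1,000 mRNAs,
4 cases vs 4 controls, 10% of circRNAs planted at fold change 4), then run
the analysis:

```r
library(cernascope)

cfg <- simulation_config(n_circ = 200, n_mirna = 50, n_mrna = 1000,
                         mirna_outdegree_range = c(5, 20), seed = 42)
sim <- generate_expression(cfg)
de <- lapply(sim$expression,
             \(x) call_de(quantile_normalize(x), sim$samples))
sapply(de, \(d) sum(d$direction != "none"))
#> circRNA   miRNA    mRNA
#>      22       0     169

concordance_table(de$circRNA, de$miRNA, de$mRNA,
                  sim$maps$circ2mir, sim$maps$mir2mrna, "up")
#>   analysis           a     b     c     d odds_ratio  p_value adjusted_or
#> 1 miRNA->mRNA        0     0    77   923         NA 1   e+ 0        NA
#> 2 circRNA->miRNA     0    27     0    23         NA 1   e+ 0        NA
#> 3 circRNA->mRNA     89   227     3   681         89 3.62e-45        89.0
```

Reading the output: all 20 planted circRNAs (plus 2 background calls) are
recovered; the miRNA layer has **no** dysregulated features, so the
miRNA→mRNA and circRNA→miRNA tables are degenerate (undefined OR, p = 1) —
the sponge leaves miRNA abundance unchanged — while mRNAs downstream of
up-regulated circRNAs are strongly enriched for up-regulation (OR = 89,
p ≈ 4e-45, essentially unchanged after miRNA adjustment).

```r
net <- build_network(de$circRNA, de$mRNA,
                     sim$maps$circ2mir, sim$maps$mir2mrna, "up")
summarize_network(net)
#> <cerna_network_summary>
#>   136 triples: 12 circRNA, 24 miRNA, 89 mRNA
#>   degree    median    q1    q3   max
#> 1 mirna_in       1     1  1.25     2
#> 2 mirna_out      4     3  6       10
#> 3 mrna_in        1     1  1        3
export_network(net, "net_up", de$circRNA, de$mRNA)  # SIF + GraphML + attrs
```

`run_pipeline(list(simulation = list(seed = 42)), "out/")` chains every
stage and writes a `manifest.json` with parameters, per-stage counts and an
MD5 hash per output file; re-running the same configuration reproduces
byte-identical outputs. `time_specificity()` / `specificity_from_counts()`
summarize how much dysregulation is specific to one of two time points, and
`plot_volcano()`, `autoplot()` on a network summary, and `plot_enrichment()`
cover the standard figures.

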