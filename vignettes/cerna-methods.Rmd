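---
title: "Methods: concordant dysregulation analysis of circRNA-miRNA-mRNA networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concordant dysregulation analysis of circRNA-miRNA-mRNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernascope)
```

## The model

circRNAs carry miRNA response elements (MREs) and can sequester miRNAs — the
competing-endogenous-RNA or "sponge" mechanism. Sequestration changes miRNA
*availability* rather than miRNA *abundance*, which yields two testable
predictions for a two-group expression study across three RNA layers:

1. mRNAs downstream of a dysregulated circRNA (via a bridging miRNA) should be
   enriched for dysregulation in the **same** direction as the circRNA
   (an up-regulated sponge disinhibits its indirect targets);
2. the miRNA layer itself should show **no** association with circRNA
   dysregulation.

`cernascope` implements the full analysis that tests these predictions:
differential expression (DE) under a joint fold-change/rank-test rule,
composition of circRNA→miRNA and miRNA→mRNA target maps, 2×2 contingency
statistics on "relevant dysregulation", direction-concordant network
construction, and annotation enrichment of the network mRNAs — plus a
synthetic-data generator with planted sponge effects so every stage can be
validated against a known truth.

## Differential expression at n = 4 vs 4

A feature is *dysregulated* when its fold change (case group mean over control
group mean, linear scale) is at least 1.5 — or at most 1/1.5 — **and** its
two-sided Mann–Whitney p-value is at most 0.05. Both thresholds are arguments
of `call_de()`.

The Mann–Whitney p-value is computed **exactly** by enumerating all
$\binom{n_1+n_2}{n_1}$ assignments of the pooled (mid)ranks whenever
$n_1+n_2 \le 12$. At 4 vs 4 there are 70 assignments, the attainable
two-sided p-values are $\{2,4,8,14,24,34,48,62\}/70$ and 1, and the minimum is
$2/70 \approx 0.029$ — so a call at $p \le 0.05$ requires complete separation
of the two groups. Ties are handled by enumerating midrank statistics
(the reference distribution is conditional on the observed tie pattern);
above 12 total samples a tie-corrected normal approximation takes over. The
two-sided p-value is the smaller tail doubled and capped at 1 (equal-tail
convention); discrete rank distributions admit other two-sided definitions,
and this one was chosen because it coincides with the exact two-sided
`wilcox.test` p-value for untied data.

Fold change is a ratio of arithmetic group means of normalized linear-scale
intensities, matching how averaged normalized signals are usually plotted; a
geometric-mean variant is available behind `log_scale_fc = TRUE`.
Benjamini–Hochberg FDR over all features in a matrix is reported for
transparency but is **not** part of the selection rule: at these sample sizes
the discrete p-value floor makes raw-p + fold-change the operative criterion.
Features with nonpositive group means are excluded from calling (with a
warning) rather than imputed.

`quantile_normalize()` forces every sample column to the identical sorted
multiset (rank-wise means across columns). Tie ranks are resolved
order-based, which preserves the multiset postcondition exactly; for
continuous intensities ties are measure-zero.

## Contingency statistics and "relevant dysregulation"

For a set of dysregulated upstream features, each downstream feature is
cross-classified by *targeted* (reachable from at least one dysregulated
upstream feature) and *relevantly dysregulated*. "Relevant" depends on the
relation: **opposite** direction for direct miRNA→mRNA targets and for
circRNA→miRNA, **same** direction for mRNAs downstream of a circRNA via a
bridging miRNA. `odds_ratio_test()` reports the cross-product odds ratio with
a Woolf (log-normal) 95% CI and a Pearson chi-square p-value without
continuity correction. Zero cells trigger a flagged Haldane–Anscombe +0.5
correction for the OR/CI only; a zero row or column margin means the table
carries no information, so the OR is undefined and p = 1 rather than an error.

The universe defaults to **all assayed downstream features**. The choice of
universe is genuinely open (published marginals rarely pin it down), so it is
an explicit argument everywhere.

`adjusted_logistic()` refits the circRNA association as a logistic regression
with two binary predictors — circRNA-targeted and miRNA-targeted — and
returns the Wald CI and p for the circRNA indicator. Both predictors are
always included (a univariate screen adds nothing with two predictors); a
constant miRNA indicator is dropped, reducing to the univariate fit. Under
(quasi-)complete separation the ML estimate diverges, so the package
substitutes a Firth-penalized fit (Jeffreys-prior modified score, implemented
in-package) and flags it.

## Regulatory networks

A regulatory triple is a tuple (circRNA, miRNA, mRNA) with the circRNA
dysregulated, both map edges present, and the mRNA dysregulated in the same
direction; the miRNA's own DE status is ignored by design. Triples are
tuple-distinct — one (circRNA, mRNA) pair reached via two miRNAs counts
twice — because published triple counts exceed distinct-mRNA counts only
under that convention. Networks are built per (time point, direction).
Summaries use R's default interpolating quantile (type 7), which is what
produces fractional IQR endpoints such as 54.25. Exports are Cytoscape-ready:
SIF (`sponges` / `targets` interactions), a node-attribute TSV, and GraphML
that round-trips losslessly for networks built by `build_network()` (such
networks are closed under the miRNA join of their own edge projection).

## Enrichment

`enrich()` is flat over-representation analysis: fold enrichment
$(k/n)/(K/N)$ and a one-sided exact hypergeometric (Fisher) p-value, with a
chi-square option. The background defaults to all assayed mRNAs, not the
genome. Terms with zero hits are excluded from the BH-FDR family — they are
untestable for over-representation and would only dilute it. `top_terms()`
ranks significant terms (p < 0.05 and FDR < 0.05) by descending fold
enrichment within each namespace, ties broken by ascending p then term id.
No GO-graph ancestry propagation is attempted; this is deliberately flat set
enrichment.

## The synthetic-data generator

`simulation_config()` + `generate_expression()` emulate a two-group,
three-layer microarray comparison:

* **Intensity model.** Per-feature baselines are drawn uniformly on a log2
  interval (default 6–12) and intensities are $2^{\mathcal{N}(\mu, \sigma)}$
  with $\sigma$ = `noise_sd` = 0.25 log2 units. Published designs of this
  kind rarely state their array variance, so the default is a free choice:
  0.25 makes a 2-fold planted change a ~4-standard-deviation shift, i.e.
  detectable but not trivially so at n = 4 vs 4.
* **Topology.** Each circRNA gets 1–`mre_cap` (default 5) miRNA partners;
  each miRNA gets an mRNA out-degree drawn from `mirna_outdegree_range`
  (default 10–50 at the default layer sizes). In-degrees are emergent.
* **Planted effects.** Default layer sizes 1,000/100/5,000 are a 1:0.1:5
  scale model of a 14,119 / 326 / 39,429 array; 5% of circRNAs are planted
  up and 5% down at fold change 4. Each downstream mRNA receives the
  concordant 2-fold effect with probability `penetrance` = 0.5; miRNA means
  are never shifted. mRNAs outside the downstream closure are background-
  dysregulated with random sign at rate `background_de_rate` (default 1%),
  using the same effect size. An mRNA reachable from both planted directions
  is assigned one direction at random. The truth record lists every planted
  and affected feature.
* **Reproducibility.** All randomness flows through named sub-streams
  derived once from the master seed, so enlarging one layer never perturbs
  another layer's draws, and identical configurations are byte-identical.

What the generator does *not* emulate: probe-level artifacts, RNase R
enrichment bias, correlated (batch) noise, mean–variance dependence, and
kinetic sponge dynamics — propagation is a direct mean shift, because the
downstream analysis only consumes direction concordance. Passing tests on
synthetic data therefore validate the statistical machinery and its
direction logic, not microarray preprocessing.

## Validation strategy and problem sizes

The test suite checks each statistic against an independent brute-force
oracle: complete enumeration for the exact rank test, direct formulas for
OR/CI/chi-square, a double/triple loop for map composition and network
construction, and direct hypergeometric summation for enrichment. Monte-Carlo
suites run the full pipeline on simulated data: 50 seeds at the default
1,000/100/5,000 scale for the sponge-asymmetry property (circRNA→mRNA OR
significant, circRNA→miRNA not), 200 replicate universes for chi-square null
calibration (no planted effects, an arbitrary circRNA set as "dysregulated",
background DE at 30% so the cells are well filled), and 50 seeds for planted-
term enrichment recovery. These sizes keep the whole suite under a few
minutes while leaving the binomial error on each estimated fraction far below
the margins being asserted.

`scripts/acceptance.R` recomputes the same quantities from scratch against
the installed package; see the README.

## Known limitations

* The exact test enumerates up to 12 total samples; beyond that the normal
  approximation is used even though moderate n can still be borderline.
* Identifier matching is exact string equality; no alias resolution.
* The logistic adjustment assumes two binary predictors; richer covariates
  (e.g. expression level) are out of scope.
* Enrichment treats annotation terms as flat sets; parent/child GO terms are
  tested independently.
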