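# gsarep

Sample-size reproducibility and specificity benchmarking for gene set
analysis (GSA).

## What problem this solves

When a GSA method (ORA, GSEA, PLAGE, …) reports a list of differentially
enriched gene sets, how much of that list is a property of the biology and
how much a property of *which* samples happened to be in the study? `gsarep`
answers this with a subsampling design: from one large case–control
expression study `D` (`n_C` controls, `n_T` cases), it draws *m* balanced
replicate datasets of size 2×n — n controls and n cases, sampled without
replacement — runs a GSA method on each, and measures

- **reproducibility** as the Jaccard overlap
  `J(S_i, S_j) = |S_i ∩ S_j| / |S_i ∪ S_j|` between the significant-set
  calls of every replicate pair (m(m−1)/2 scores per size, the *overlap
  matrix* / multiset `P_(2×n)`), plus the overlap of each replicate against
  the whole-dataset analysis (`W_(2×n)`);
- **rank agreement** as Kendall's coefficient of concordance W (tie-corrected)
  over the adjusted-p rankings of every gene set called significant in at
  least one replicate;
- **specificity** with a control-control design: both pseudo-groups drawn
  from actual controls only, so every significant call is a false positive.

All methods pass through one harmonized significance pipeline — raw per-set
p → Benjamini–Hochberg across the database → strict α = 0.05 — so
differences between methods are differences in their statistics, not in
their multiplicity handling. Sweeping n (default 3…20, m = 10) reveals the
central empirical pattern: *reproducibility rises with sample size*, and
shows where each method becomes usable — e.g. sample-permutation GSEA at
2×3 has only C(6,3) = 20 balanced relabellings, so its smallest non-zero
p-value is 0.05 and it can never call anything significant there.

Six methods are built in behind a uniform interface (`ora`, `page`,
`plage`, `ssgsea`, `gsea_g`, `gsea_s`); external tools plug in through a
simple executable contract. A synthetic expression generator with known
embedded enrichment makes the whole pipeline testable end-to-end without
any microarray downloads. Results are visualized as *pine plots* — stacked
triangular heat-map layers, one per sample size, blue (0) → yellow (0.5) →
red (1) — plus overlap box plots, concordance curves and mean-count plots.

## Worked example

```r
library(gsarep)

sim <- generate_dataset(synthetic_config(seed = 1))
sim$dataset
#> ExpressionDataset: 1000 genes x 60 samples (30 control, 30 case)
sim$database
#> GeneSetDatabase: 100 sets (median size 33)

for (n in c(3, 10, 15)) {
  reps  <- generate_replicate_series(sim$dataset, n, 10, "case_control", root_seed = 1)
  runs  <- lapply(reps, function(r) run_gsa(r, sim$database, "ora"))
  calls <- lapply(runs, `[[`, "call")
  pm    <- pairwise_overlap_multiset(calls, "ora", n)
  cw    <- kendalls_w(lapply(runs, `[[`, "result"), calls)
  cat(sprintf("n = %2d: mean pairwise overlap = %.3f, Kendall W = %s, mean |S| = %.1f\n",
              n, mean(pm), if (cw$defined) sprintf("%.3f", cw$W) else "undefined",
              mean(lengths(lapply(calls, `[[`, "significant")))))
}
#> n =  3: mean pairwise overlap = 0.000, Kendall W = undefined, mean |S| = 0.0
#> n = 10: mean pairwise overlap = 0.935, Kendall W = 0.999, mean |S| = 10.5
#> n = 15: mean pairwise overlap = 0.851, Kendall W = 0.973, mean |S| = 11.1
```

At n = 3 the replicates are too small for any gene to survive the BH-based
DE cutoff, so ORA calls nothing and demonstrates no reproducible finding
(overlap 0; W undefined). By n = 10 the ten truly enriched sets are
recovered almost identically in every replicate (overlap 0.93, W ≈ 1); the
mean call size of ~10–11 matches the 10 sets the generator actually
enriched, with the excess coming from random sets that share shifted genes.

`run_sweep(sweep_config(...))` runs the full grid (both modes, all sizes,
several methods) and writes every table as TSV — replicate manifests,
per-replicate results, overlap matrices/multisets, concordance,
Kruskal–Wallis across sizes, mean counts — plus the figures and a JSON
manifest; rerunning with the same config and seed reproduces the tables
byte-for-byte.

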