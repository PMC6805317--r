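---
title: "Benchmarking the reproducibility and specificity of gene set analysis across sample sizes"
author: "gsarep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking the reproducibility and specificity of gene set analysis across sample sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsarep)
```

## The problem

Gene set analysis (GSA) asks whether predefined groups of genes — GO terms,
pathways — behave differently between two conditions. Its answers drive
biological interpretation, yet they depend on an experimental design choice
that is rarely examined: the number of samples per group. If two labs run the
same GSA method on two equally sized cohorts drawn from the same population,
how similar are the lists of "differentially enriched" gene sets they report?
And when there is no biological difference at all, how often does a method
report enrichment anyway?

`gsarep` makes both questions measurable with a subsampling design that
holds every confounder fixed. From one large case–control expression study
`D` with `n_C` controls and `n_T` cases (both large), it draws *replicate
datasets* of size 2×n — n controls and n cases sampled without replacement —
so that platform, protocol, tissue and processing are identical across
replicates and only the sampled individuals differ. Repeating the draw m
times per size and sweeping n reveals how agreement between same-size
analyses changes with sample size.

## The procedure

For each sample size n and each GSA method ψ:

1. Draw m replicate datasets `D_i^(2×n)` (default m = 10, n from 3 to 20).
2. Run ψ on each replicate against the gene set database; store the per-set
   p-values in a vector aligned to the database order.
3. Apply the identical significance pipeline to every method: raw p →
   Benjamini–Hochberg adjustment across the database → strict α = 0.05 call.
   Harmonizing multiplicity control is what makes methods comparable; no
   method's native FDR machinery is reproduced.
4. Score agreement between replicates i and j by the Jaccard overlap
   `J(S_i, S_j) = |S_i ∩ S_j| / |S_i ∪ S_j|` of their significant calls.
   The m(m−1)/2 pairwise scores per size form an upper-triangular *overlap
   matrix* (diagonal fixed at 1 as a visual reference) and, flattened, the
   pairwise overlap multiset `P_(2×n)`. The m overlaps against the
   whole-dataset analysis form `W_(2×n)`, which asks whether 2×n samples
   already reproduce the full-cohort result.
5. Measure rank agreement with Kendall's coefficient of concordance over the
   union U of sets called significant in at least one replicate; each
   replicate ranks all of U by its adjusted p-values (every set always has
   one, so nothing is imputed), mid-ranks for ties, and W uses the
   tie-corrected form `W = 12·S / (m²(k³−k) − m·ΣT)`.
6. Test whether overlap distributions differ across sizes with a
   tie-corrected Kruskal–Wallis test over `P_(2×3) … P_(2×20)`.

The *control-control* variant draws both pseudo-groups from the parent's
controls (2n distinct controls, n relabelled "case"; requires n < n_C/2).
There is no signal by construction, so the mean number of significant calls
per size is a direct false-positive measurement.

## The 0/0 overlap convention

The Jaccard formula is undefined when both calls are empty. `gsarep` scores
that case 0 by default: an analysis that reports nothing has demonstrated no
reproducible finding, and treating mutual silence as perfect agreement would
make a method that is simply powerless at small n look maximally
reproducible there — precisely inverting the quantity this framework
measures. The clearest case is sample-permutation GSEA at 2×3, which cannot
call anything significant (see below) and should sit at the *bottom* of the
overlap scale, not the top. The opposite convention is one argument away
(`jaccard_overlap(a, b, empty_value = 1)`), and the influence of the choice
is auditable by counting empty calls in the per-replicate result tables.

## Built-in methods

Six methods cover the main methodological families; all consume a replicate
plus the gene set database and return one raw p per set, in database order.
Sets with no member in the expression background get p = 1 and a flag.

* **ORA** — genes with BH-adjusted Welch p below 0.05 form the DE list; each
  set's p is the upper-tail hypergeometric probability of the achieved
  overlap (the DE cutoff is exposed as `de_threshold`; 0.05 is this
  package's choice, as over-representation pipelines do not share a single
  convention).
* **PAGE** — Z = (Sm − μ)·√m/δ where Sm is the set's mean per-gene effect
  (case-minus-control mean log2 difference), μ and δ the mean and SD of all
  genes' effects; two-sided normal p.
* **PLAGE** — per set, the *metagene*: the first right-singular vector of
  the standardized member × sample submatrix; p from a two-sample t-test of
  metagene values between conditions. Zero-variance member rows contribute
  zeros; the metagene's arbitrary sign cannot change the two-sided p.
* **ssGSEA** — per sample, genes ranked descending (top rank value N); the
  set score is the summed difference between the rank-weighted in-set
  cumulative (weights rank^τ, τ = 0.25) and the uniform out-of-set
  cumulative. Computed in closed form (the summed ECDF difference reduces to
  `Σ_hit r^(τ+1)/Σ_hit r^τ − Σ_miss r/(N−k)`); p from a two-sample t-test of
  per-sample scores.
* **GSEA-G** — weighted Kolmogorov–Smirnov enrichment score (hits add
  |t|^p/N_R, misses subtract 1/(N−N_hits); ES is the signed maximum
  deviation) against a null of random same-size gene subsets, with the
  add-one estimator `(1 + #{|ES_null| ≥ |ES_obs|})/(1 + n_perm)` so p is
  never zero. Permutations are shared between equal-size sets.
* **GSEA-S** — the same score, but the null recomputes the whole gene
  ranking under balanced relabellings (choose n of the 2n samples as
  pseudo-controls). When C(2n, n) ≤ 5000 all relabellings are enumerated and
  the identity is part of the null, so p ≥ 1/C(2n, n).

The per-gene statistic feeding ORA, PAGE and both GSEA rankings is Welch's
unequal-variance t (robust, stated openly — published tools differ
internally); a gene constant and equal in both groups gets t = 0, p = 1.
Score-based methods (PLAGE, ssGSEA) compare per-sample scores with a
two-sample t-test; this is an explicit package choice, since the upstream
literature does not fix how per-sample scores become per-set p-values.
External methods plug in through an executable contract
(`make_external_gsa_method`) and pass through the identical BH + α pipeline.

### Why 2×3 sample permutation can never be significant

With 3 controls and 3 cases there are C(6,3) = 20 balanced relabellings, so
the smallest non-zero permutation p-value is 1/20 = 0.05 — and the strict
`adjusted p < 0.05` call can never fire. This combinatorial floor, not any
property of the data, is why sample-permutation GSEA reports nothing at very
small sizes; the exhaustive mode makes the floor exact rather than an
artifact of Monte Carlo resolution. One subtlety of the undirected |ES|
comparison used here: the complement of the true labelling mirrors the
ranking, so a symmetric enriched set often attains 2/20 rather than 1/20;
the floor itself is unchanged.

## The synthetic study generator

Real GEO-scale datasets cannot ship with a package, so `gsarep` includes a
generator whose *defaults define a fixed desk-scale study*: 1000 genes, 30
controls + 30 cases, 100 gene sets of 10–50 members, 10% of sets truly
enriched, a 1.5 log2-unit shift applied to all members of enriched sets in
cases, within-set correlation ρ = 0.1, noise SD 0.4, baselines uniform on
[4, 10]. The model for gene g, sample s is

```
x_gs = b_g + √ρ · L_{set(g),s} + √(1−ρ) · σ · ε_gs + Δ_gs
```

with one standard-normal latent factor L per (set, sample) inducing
correlation ρ among members (genes in several sets follow their first
containing set; a simple, documented rule), independent Gaussian noise, and
Δ the condition shift. Parameter rationale:

* `noise_sd = 0.4` — a typical within-condition log2 SD for expressed genes
  on RMA-normalized arrays; it puts the n = 3 … 20 sweep in the regime real
  studies occupy, where small replicates find some but not all signal.
* `effect_size = 1.5` (≈ 2.8-fold) — a strong but common differential signal
  of the kind large case–control contrasts exhibit.
* `rho = 0.1` — mild co-expression; reviewers of GSA simulations warn
  against zero-correlation designs, so correlation is a first-class knob
  rather than an afterthought.

`generate_null_dataset()` forces the effect to zero and labels every sample
control, producing the pool for control-control sweeps. Everything is a
deterministic function of one integer seed (R's Mersenne–Twister driven
from the root seed; per-replicate seeds are derived by a stable integer mix
of (root seed, mode, n, replicate index), so adding sample sizes never
perturbs earlier draws).

What the generator deliberately does **not** emulate: probe-level structure,
batch effects, heteroskedastic per-gene variances, heavy-tailed intensity
distributions, or realistic gene-set overlap topology. Passing tests on this
model therefore demonstrate correctness of the *pipeline machinery and its
statistics under a known truth* — not that any method is well-calibrated on
real microarray data.

## Numerical choices and degenerate inputs

* Enrichment-score ties: the running sum's extremes are evaluated only at
  positions adjacent to hits (between hits it is monotone); on a magnitude
  tie within 1e−12 the earlier ranked position wins. Ties are not rare once
  the weight exponent is 0.
* Ranking-statistic ties are broken by input gene order (stable sort).
* BH adjustment delegates to `stats::p.adjust(method = "BH")`;
  Kruskal–Wallis to `stats::kruskal.test` (chi-square approximation — group
  sizes of 45 at the default m = 10 are ample); the hypergeometric tail to
  `stats::phyper`. Kendall's W and all set-level method logic are
  implemented here.
* Degenerate score vectors (all per-sample scores equal) yield p = 1; a
  gene set covering the whole background is an error for ssGSEA/GSEA (the
  out-of-set walk is undefined); an all-constant expression matrix is an
  error for PAGE ("degenerate gene-level effects").
* Kendall's W is undefined when fewer than two gene sets were ever called
  significant; such points are reported as undefined and omitted from plots
  with a note.
* Max-mean probe collapsing breaks mean ties by input order, so results do
  not depend on hash or sort instability.
* Replicates are not forced to be mutually distinct — with realistic parent
  sizes collisions are vanishingly rare, and recorded indices/seeds make
  them detectable.

## Problem sizes used in the shipped checks

The package's own test-and-verification runs use desk-scale instances chosen
to exercise every code path at comfortable interactive speed: oracle
comparisons on backgrounds of ≤ 25 genes and vectors of ≤ 50 p-values;
calibration on a 600-gene null dataset with 500 random 20-gene sets
(exhaustive 252-relabelling GSEA-S included); the reproducibility trend on
ten independent default-size synthetic studies with m = 5 at n ∈ {3, 15};
specificity on a 22-control pool at n ∈ {3, 5, 10}. A full default sweep
(18 sizes × 10 replicates × several methods) on the default synthetic study
runs in minutes on one CPU.

## Known limitations

* Only balanced replicate designs are implemented; the effect of group-size
  imbalance is outside the current scope.
* Sensitivity/power against a biological gold standard is not measured —
  on real data no complete truth exists, and on synthetic data it would
  mostly restate the generator's assumptions.
* The six built-ins are faithful to their published formulas but are not
  drop-in numerical replicas of any specific tool release; published tools
  differ in gene-level statistics, tie handling and default filters, which
  is one of the reasons a uniform pipeline is needed in the first place.
* Conclusions about *which* method is most reproducible on *real* data
  require running the sweep on real cohorts; the synthetic defaults only
  certify the machinery.
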