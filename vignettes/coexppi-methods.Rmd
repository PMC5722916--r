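---
title: "Methods: co-expression modules, enrichment tests and PPI bottlenecks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules, enrichment tests and PPI bottlenecks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexppi)
```

## What the package computes

`coexppi` takes a gene-level RNA-seq count matrix for samples spanning
several cell types and produces, in order:

1. **TPM-normalized expression.** Counts are divided by gene length (per
   kilobase) and then by the per-sample sum of those rates, scaled to 1e6,
   so each library sums to exactly one million and values are comparable
   across genes and samples. Technical replicates are summed on the raw
   count scale beforehand; analysis happens on `log2(TPM + 1)`.
2. **Weighted co-expression modules.** A signed-hybrid adjacency
   (`cor^beta` for positive correlations, 0 otherwise) at a soft-threshold
   power chosen by scale-free model fit; topological overlap (TOM) as the
   similarity; average-linkage clustering of `1 - TOM`; an adaptive tree
   cut; eigengene-correlation merging (> 0.75); module eigengenes (first
   principal component of the standardized members); K_ME membership
   (gene-eigengene correlation, > 0.75 grants possibly-multiple
   membership); and module-trait correlations against a binary sample x
   cell-type design with Student-t p-values.
3. **Enrichment statistics.** Hypergeometric upper-tail tests for
   tissue-specific gene sets and GMT collections (with the
   FDR <= 0.05 / fold >= 1.5 / >= 5 genes filter), inclusive
   |fold-change| >= 2 and adjusted p <= 0.01 up-regulation calls from DE
   tables, and a size-matched randomization test (10,000 random modules by
   default) whose p-value counts null modules with *strictly more* overlap
   than observed.
4. **PPI bottlenecks.** A STRING-style edge list is thresholded at combined
   score >= 0.7 over the co-expressed genes, the largest connected component
   is extracted, nodes are scored by unnormalized shortest-path betweenness,
   and the genes at or above the 95th percentile are called bottlenecks.

Every stage is exported on its own; `run_pipeline()` composes them, writes
each intermediate as TSV, and emits a JSON manifest of md5 checksums so a
rerun with the same configuration and seed is byte-identical.

## The synthetic-data generator

Public expression repositories cannot provide ground truth for any of the
stages above, so the package ships a generator
(`simulate_expression()`, `simulate_ppi()`) whose defaults define the
design used throughout the tests: 6 cell types, 26 biological replicates in
total (5, 5, 4, 4, 4, 4), 2,000 genes, and 5 planted modules of 50 genes at
a target within-module correlation of 0.81.

The construction, per module `m` and sample `s` of cell type `t`:

* latent activity `e = A[m, t] + N(0, 1)`, with the default activity grid
  `A` giving module `m` a mean of 4 in cell type `m` and 0 elsewhere;
* member gene `g` has latent expression
  `a_g e + sqrt(1 - a_g^2) * noise_sd * s_m * N(0, 1)`, where the loading
  `a_g` is uniform on `sqrt(0.81) +- 0.1` and `s_m` is the standard
  deviation of the module's activity over the whole design. Scaling the
  noise by `s_m` makes the pairwise latent correlation of two members
  exactly `a_g a_h` whatever the activity profile, so it averages the 0.81
  target; spreading the loadings gives each module the hub-to-periphery
  connectivity gradient real co-expression modules show, which is what lets
  a soft-thresholded network of this data reach a scale-free fit of
  R^2 >= 0.9. With identical loadings the degree distribution is bimodal
  and no power attains that fit;
* background genes are independent `N(0, 0.5)` noise — less variable across
  samples than module genes, whose activity moves with cell type. This is
  the property that makes top-quartile variance selection informative, and
  it holds in real data for the same reason;
* counts are Poisson with rate proportional to
  `depth * length_kb * softplus(latent)`, rescaled per sample so the
  expected library size is the configured depth (1e6). The softplus link
  keeps rates positive without truncating the planted correlation
  structure. A negative-binomial option is not provided; Poisson noise at
  this depth is already negligible relative to the planted biology, which
  is what the machinery under test consumes;
* differentially expressed genes (5% of genes, |log2 FC| = 2, alternating
  sign) are drawn from the *background* and shifted in the first contrast
  cell type. The default contrast is cell type 6 vs 1: under the default
  activity grid no planted module is driven by cell type 6, so the planted
  DE genes — which genuinely co-express through their shared shift — do not
  masquerade as an extra copy of a planted module. Tissue-specific labels
  (30 genes per tissue, tissues named after the cell types) are assigned
  disjointly at random;
* `simulate_ppi()` builds one dense community per requested size over the
  genes of the first planted modules (a deterministic spanning path plus
  Erdos-Renyi extras at `p_in = 0.9`, scores uniform in [0.7, 1]), joins
  them through a single bridge gene with **two** edges into each community,
  and adds decoy edges scored below 0.7. With one attachment per community
  the attachment nodes are cut vertices and can out-score the bridge by
  their intra-community path share; with two attachments the bridge alone
  carries every cross-community shortest path and is the betweenness
  maximum by construction. The bridge is taken from the first module not
  hosting a community, so a network-wide PPI analysis over co-expressed
  genes sees it.

Everything is generated inside `withr::with_seed`, so a configuration plus
seed is reproduced byte-for-byte.

What the generator does *not* emulate: batch effects, library-preparation
covariates, overdispersion beyond Poisson, correlated background
(housekeeping) programs, overlapping planted modules, and
identifier-mapping noise between protein and gene namespaces. Tests passing
on this design therefore demonstrate that the machinery recovers the
structure it assumes, not that the assumptions hold in any particular real
dataset.

## Numerical and procedural choices

* **"TPM > 1" filter.** Applied to the per-gene *mean* TPM across samples,
  strict inequality; `rule = "any_sample"` / `"all_samples"` are available.
  A single-number-per-gene rule is the only variant that yields one
  reproducible gene count.
* **Top quartile.** `floor(n/4)` genes by unbiased (n-1) sample variance of
  `log2(TPM + 1)`; 19,261 genes give exactly 4,815. Ties at the cut break
  lexicographically by gene id, making selection invariant to row order.
* **Soft threshold.** Candidates `1:10, 12, 14, ..., 20`; the smallest power
  whose scale-free R^2 reaches 0.9 wins; if none does, the best power is
  used and flagged. The fit bins connectivity into 10 equal-width bins and
  regresses `log10 p(k)` on `log10 mean-k` over non-empty, nonzero bins;
  at least two such bins are required, otherwise the fit errors.
* **Tree cut.** The dynamic-cut literature offers several variants with
  tuning parameters; this package uses a deterministic adaptive cut: every
  gap between consecutive merge heights is a candidate level, and the tree
  is cut where the number of clusters of at least `min_module_size` (30)
  genes is maximal, largest height among ties. A fixed-quantile cut (e.g.
  at the 0.99 quantile of merge heights) was rejected: with TOM near 0
  between unrelated genes, merge heights saturate just below 1 and any
  quantile rule lands in that noise regime, fusing unrelated groups.
  Because the largest-height tie-break takes each cluster at its fullest
  extent, `detect_modules()` afterwards unassigns clustered genes whose
  K_ME to their own module does not exceed the membership threshold — the
  standard practice of removing genes that do not track their module's
  eigengene.
* **Eigengene.** First right-singular vector of the row-standardized member
  matrix, unit norm, oriented to correlate positively with the mean member
  profile (the sign of a singular vector is otherwise arbitrary).
  Zero-variance members are excluded with a warning.
* **Merging.** The most-correlated eigengene pair above 0.75 merges first
  and eigengenes are recomputed before the next pass, making the `> 0.75`
  rule order-independent; the module count strictly decreases, so the loop
  terminates.
* **Module-trait correlation.** Pearson correlation between eigengene and
  the binary cell-type indicator, two-sided p from
  `t = r sqrt(n-2)/sqrt(1-r^2)` on `n - 2` df; p-values are reported
  unadjusted (the module-level BH adjustment is available as `bh_fdr()`).
  An alternative reading — a group-mean contrast instead of the indicator
  correlation — is *not* implemented.
* **Randomization p.** `#(null > observed)/n_random`, the strictly-greater
  convention; a reported 0 prints as `< 1/n_random`. The strictly-greater
  count combined with the discreteness of the overlap distribution puts the
  null rejection rate at the 0.05 level near 0.055 rather than below 0.05;
  `convention = "geq"` gives the conservative variant.
* **Hypergeometric tail.** Computed via the log-scale distribution function
  (`log_p = TRUE` returns the log directly); tails far below the double
  underflow limit (~1e-308) are representable only on the log scale, which
  is also how the test suite compares against its summation oracle.
* **Bottleneck percentile.** R's default (type-7) quantile with inclusive
  `>=`: 20 distinct scores yield exactly the top one; all-equal scores make
  every node a bottleneck. Percentiles are invariant to monotone rescaling,
  so normalizing betweenness first would not change the called set.
* **PPI edge handling.** STRING-scale scores (0-1000) are divided by 1000;
  duplicate records of an unordered pair keep the maximum score (the
  conservative superset under thresholding); self-edges are dropped.
  Largest-component ties go to the component holding the lexicographically
  smallest node.
* **Seeding.** Every stochastic entry point takes a mandatory seed;
  `run_pipeline()` expands its single seed into per-stage seeds by fixed
  offsets, so adding a stage never perturbs the streams of earlier stages.
  The manifest contains only deterministic content (config hash, seed, md5
  checksums, package version, warnings); wall-clock timestamps go to the
  stderr log, not the manifest, so reruns are byte-identical.

## Problem sizes used by the tests

The test suite and the acceptance script run the full design (2,000 genes,
26 samples, 5 x 50-gene modules) for module recovery — 20 independent seeds
— and smaller instances (300-500 genes, 2 modules) where only a planted
bridge or TPM arithmetic is at stake. Betweenness is verified against
exhaustive shortest-path enumeration on 100 random graphs of at most 12
nodes, where enumeration is exact and fast; the hypergeometric tail against
a 1,000-quadruple log-space summation including the 19,628/354 population
of the protein-atlas placenta set; and the randomization test against its
exact enumerable null on a 6-gene universe plus a 200-replicate calibration
run at 10,000 draws each.

## Known limitations

* The dynamic-cut variant is this package's own deterministic rule, not a
  reimplementation of any published dynamic hybrid algorithm; on data whose
  modules only separate at nested heights it will be cruder than the
  hybrid's stage-wise refinement.
* Signed (non-hybrid) networks, block-wise decomposition for very large
  gene sets, consensus networks, weighted-shortest-path betweenness and
  GSEA-style ranked statistics are out of scope.
* Inputs must share one identifier namespace; no protein-to-gene mapping is
  attempted.
* Missing expression values are rejected rather than imputed, matching
  counting-pipeline output.
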