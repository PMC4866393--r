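---
title: "Detecting modular rewiring of coexpression networks across a condition boundary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting modular rewiring of coexpression networks across a condition boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexshift)
```

## The question the package answers

A developmental transcriptome can change in two very different ways across a
sharp boundary such as birth. Either the same gene networks stay wired
together and merely shift their expression levels, or the wiring itself — who
is correlated with whom — is rebuilt. `coexshift` implements the full
analysis that distinguishes these possibilities for any gene × sample
expression matrix with a two-level condition window (the canonical example
being prenatal vs postnatal brain samples across several regions and ages):

1. **Global comparison.** PCA of samples with a Kruskal–Wallis test of PC1
   against candidate factors; average-linkage clustering of per-stratum mean
   expression profiles; and average-linkage clustering of whole per-stratum
   *coexpression matrices* under the distance $d = 1 - R$, where $R$ is the
   Pearson correlation of the flattened upper triangles. If profiles split
   by condition *and* coexpression structures split by condition, the
   rewiring model is supported.
2. **Differential coexpression modules.** With per-condition correlation
   matrices $c^{(1)},c^{(2)}$, the differential adjacency is
   $d_{ij} = \left(\tfrac12\left|\,\mathrm{sign}(c^{(1)}_{ij})\,c^{(1)2}_{ij}
   - \mathrm{sign}(c^{(2)}_{ij})\,c^{(2)2}_{ij}\right|\right)^{\beta/2}$,
   with soft threshold $\beta = 6$. The $\tfrac12$ keeps $d \in [0,1]$
   (the raw signed-squared difference spans $[-2,2]$). Topological overlap
   of $D$ is clustered (UPGMA on $1-\mathrm{TOM}$), modules are cut with a
   minimum size of 100 genes and deep split enabled, and modules whose
   eigengenes (first PC of the standardized module expression, pooled over
   both windows) correlate above $r = 0.9$ are merged iteratively.
3. **Rewiring significance.** Each module's effect size is
   $\Delta = \bar r_{\text{post}} - \bar r_{\text{pre}}$ (mean
   upper-triangle correlation). Significance comes from permuting the
   condition labels of the pooled samples (1000 permutations, two-sided on
   $|\Delta|$, $p$ floored at $1/(n_{\text{perm}}+1)$).
4. **Functional characterization.** Per module, gene-set enrichment by a
   Z-score test whose null mean/sd come from 10,000 equally-sized random
   draws from the background; BH-FDR within module; significance requires
   FDR < 0.05 *and* observed − expected > 1. A hypergeometric tail test is
   the closed-form alternative. Motif exclusivity across modules is tested
   by permutation (10,000 draws preserving enriched-set sizes).
5. **Edge anatomy.** Within a module, gene pairs with $r > 0.95$ in either
   condition are classified `prenatal_only` / `postnatal_only` / `constant`
   and exported as GraphML/TSV with per-condition degrees.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `beta` | 6 | soft-threshold exponent on the adjacency difference; larger values suppress weak correlation changes |
| `min_module_size` | 100 genes | smallest reportable module |
| `merge_r` | 0.9 | eigengene correlation above which modules merge |
| `edge_threshold` | 0.95 | per-condition high-correlation edge cutoff |
| `n_perm_module` | 1000 | rewiring permutations (p resolution 1/1001) |
| `n_samples_enrichment` | 10000 | Z-score null draws |
| `min_term_size` | 150 genes | term-size floor for untargeted enrichment |
| `alpha` | 0.05 | FDR threshold |

All are exposed through `coex_config()` / the `coexshift` CLI and recorded
in the run manifest.

## The synthetic world, and what a green test establishes

`simulate_expression()` draws, per gene $g$ and sample $s$,
$$x_{gs} = \mu_g + \rho_{g,\mathrm{region}(s)} +
  \lambda_g(\mathrm{window}(s))\, f_{m(g),s} + \varepsilon_{gs},$$
with one latent factor per module, i.i.d. $N(0,1)$ per sample, residual sd
0.3 and region-effect sd 0.3 by default. The implied within-module
correlation is $\lambda^2 / (\lambda^2 + \sigma^2)$, which the tests verify
at $n = 500$ samples. The default design mirrors the motivating study's
shape: 8 regions × 7 time points × 2 windows = 112 samples, and the default
module set plants 2 gain, 1 loss, 1 swap and 1 stable module of 150 genes
each plus 1250 background genes.

Rewiring archetypes are loading patterns: gain $(0, \lambda)$, loss
$(\lambda, 0)$, stable $(\lambda, \lambda)$. The **swap** archetype uses two
sub-blocks on one factor, A: $(\lambda, 0.3\lambda)$ and B:
$(-0.3\lambda, \lambda)$. A pure on/off swap (A $(\lambda,0)$, B
$(0,\lambda)$) would make the sub-blocks *disjoint* in the differential
network — two 75-gene components, invisible at a 100-gene size floor — which
is a property of that idealization, not of real rewiring. The chosen minor
loadings keep the sub-blocks' high-correlation windows clearly different
(mean within-block r ≈ 0.86 vs ≈ 0.35) while the cross-block correlation
flips sign across the boundary (≈ −0.55 → +0.55), so the module remains one
connected differential block, matching the two-subnetwork swap seen in real
modules.

What the generator does **not** emulate: RNA-seq count noise (values are
Gaussian on a log-like scale; an `exponentiate` flag gives RPKM-like
positives for I/O tests), temporal autocorrelation (factors are i.i.d. per
sample — every downstream statistic is a cross-sample correlation, so
trajectories add nothing to testability), library-size or batch artifacts,
and scale-free topology: the planted connectivity distribution is two-point,
so the scale-free fit index stays low on synthetic data even though the fit
computation itself is verified on a constructed power law. A green suite
therefore establishes algorithmic correctness and calibration, not that any
particular biological dataset will reproduce the motivating study's numbers.

## Numerical and design choices

* **Tree cut.** `cut_modules()` is a deliberately simple variant of dynamic
  tree cut: a branch is a module when it has ≥ `min_module_size` leaves and
  its join height exceeds its own height by
  `max(gap_min, gap_frac * height_range)` (defaults 0.01 and 0.15); nested
  candidates resolve to the innermost; `deep_split` allows one extra pass
  splitting a selected branch into two qualifying children; the dendrogram
  root is never a module (it separates nothing — this is what keeps
  structure-free null input module-free). The defaults were calibrated
  against planted-branch geometry: genuine module branches separate by
  ≥ 20 % of the height range while intra-branch gaps are two orders of
  magnitude smaller. Planted-module recovery (ARI = 1.0 across seeds in the
  acceptance suite) is this function's contract; bit-equivalence with the
  reference implementation is not claimed.
* **Permutation null.** "Permuting expression values" is ambiguous; the
  default permutes condition labels of pooled samples, preserving each
  gene's marginal distribution and testing exactly the condition-dependence
  of correlation. A value-shuffle mode (`scheme = "value"`) is available but
  destroys all correlation, making its null much easier to beat.
* **Eigengene orientation.** The first singular vector's sign is fixed by
  positive correlation with the module's mean standardized profile; PCA
  component signs are fixed by the largest-magnitude loading. All stochastic
  steps take a seed, and per-module streams are derived deterministically
  from (seed, module), so reruns are bit-identical.
* **Degenerate input.** Genes constant across all samples are removed up
  front; genes constant *within a stratum* yield NA correlations that are
  flagged and dropped pairwise. An all-tied Kruskal–Wallis input returns
  H = 0 with a warning. Enrichment terms with zero null sd are flagged
  degenerate and excluded from the BH family.
* **Memory.** TOM is computed in column blocks (`block_size = 2000`), so
  ≥ 20,000-gene inputs stay near two n × n doubles; correctness tests run at
  ≤ 2,000 genes.
* **Two-sidedness.** Rewiring p values are two-sided in |Δ|; enrichment
  z-tests report two-sided p but only over-representation
  (observed − expected > 1) can be flagged significant.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_expression(default_module_specs(), seed = 11)
chain <- diffcoex_chain(sim$expression)
table(chain$assignment)            # 4 rewired modules + unassigned
chain$rewiring                     # per-module mean r pre/post and delta
g1 <- names(chain$assignment)[chain$assignment == 1]
rewiring_permutation_test(sim$expression, g1, n_perm = 1000, seed = 1)$p
#> 0.000999001                      # the 1/1001 floor
```

## Known limitations

The tree cut is a simplified branch-gap rule; modules that overlap heavily
in TOM space (join gap below `gap_frac` of the height range) will be missed
or merged. The Z-score enrichment null resamples genes independently, so
correlated annotation structure (GO term nesting) is not modelled — terms
are taken as given at leaf level. The exclusivity null preserves set sizes
only by default; per-motif marginal frequencies are preserved only under the
`"swap"` null. Differential expression is a plain Welch t test, not a
moderated-variance model. None of the motivating study's headline numbers
are reproduced here: they depend on its specific data and annotation
snapshots, and this package's claims are the properties its tests compute.
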