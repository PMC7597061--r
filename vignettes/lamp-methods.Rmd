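---
title: "Methods: layered assessment on modules and pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered assessment on modules and pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamp)
```

## The problem and the model

Disease nomenclature is mostly anatomical; two diseases of the same
organ can have unrelated molecular mechanisms, and two diseases of
different organs can perturb the same cellular machinery. `lamp`
classifies diseases by where their genes *send* influence in a directed
gene interaction network: a disease is represented by the normalized
profile of its impact on biological pathways, and diseases with similar
profiles are grouped together regardless of anatomy or gene overlap.

The computation proceeds in five stages.

1. **Network.** Directed bait-to-prey interaction records are collapsed
   into a simple directed graph; analysis is restricted to the largest
   weakly connected component (LCC). The bow-tie decomposition splits
   the LCC around its largest strongly connected component (LSCC) into
   UP_LSCC (can reach the core, unreachable from it), DOWN_LSCC
   (reachable from the core, cannot return) and tendrils. Maximum
   bipartite matching yields the driver-node count for structural
   controllability; degree and betweenness summaries and discrete
   power-law fits describe the topology.
2. **Modules.** Louvain modularity optimization on the symmetrized LCC
   yields topological modules `M_t`.
3. **Layered scoring.** Forward BFS layers from each disease gene
   measure how quickly a module's genes are reached (IALS); reverse BFS
   layers from each pathway's genes measure how much of each upstream
   stratum a module occupies, geometrically discounted by `2^-s` (WPS).
   Their product summed over modules is the impact score `IS(D, P)`,
   min–max normalized per disease into `NIS`.
4. **Screening and clustering.** Diseases whose genes all lie in
   DOWN_LSCC form CATG-0 before any scoring-based grouping: their
   perturbations cannot feed back into the core, which makes them a
   qualitatively distinct, pharmacologically attractive group. The
   remaining NIS vectors are clustered with Ward.D2 on Euclidean
   distances and the dendrogram is cut by the difference-vector rule.
5. **Characterization.** Categories are described by Shannon entropy of
   their composition with respect to a reference classification, by
   cross-tabulation, and by Fisher over-representation of
   overlapping-gene disease pairs within categories. Declarative
   refinement overrides can add (never remove) dual memberships.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `taxon` | `build_network` | 9606 | keep human–human records only |
| `keep_self_loops` | `build_network` | `FALSE` | self-interactions carry no layer information; flag retains them |
| `seed`, `resolution` | `fast_unfolding` | —, 1.0 | Louvain tie-breaks are randomized; classic modularity |
| `reciprocal_weight` | `fast_unfolding` | `FALSE` | mutual edge pairs collapse to weight 1; flag gives weight 2 |
| decay base | `wps` | 2 | layer 0 (the pathway itself) is foremost, each further stratum counts half |
| `k_min`, `k_max` | `difference_vector_cut` | 2, `min(n-1, 40)` | candidate partition sizes |
| `pooling` | `difference_vector_cut` | `"cluster"` | see "The dendrogram cut" below |
| `perplexity`, `exaggeration`, `eta`, `max_iter` | `tsne_embed` | 30, 12, 200, 3000 | standard visualization settings for this analysis |

## Numerical and definitional choices

**IALS and layer 0.** Including a disease gene's own layer 0 in the
IALS sums would put the gene in the numerator with zero weight in the
denominator and allow division by zero; the sums therefore start at
layer 1, and a disease gene with no in-module gene at layer ≥ 1
contributes 0. This is the main interpretive choice in the scoring
kernel. The membership indicator is taken literally: only disease genes
*inside* the module contribute to that module's IALS.

**Constant NIS rows.** When a disease's IS row is constant, min–max
normalization is undefined; the row is set to all zeros so such
diseases cluster together instead of failing.

**Caching.** Forward layers depend only on the rooting gene, so the
per-gene contribution is computed once per distinct disease gene;
reverse layers are computed once per pathway. `impact_scores` exposes
the cached `IALS` and `WPS` factors, and the test suite verifies they
reproduce the one-shot kernels exactly.

**The dendrogram cut.** The difference vector compares the average
disease distance within partitions against the average distance between
partitions at each candidate k and cuts where the absolute difference
peaks (smallest k on ties). Two summaries of "average" are
implemented. Pooling all pairs globally (`pooling = "pairs"`) proved
fragile during development: past the true k the pooled Δ(k) is nearly
flat, and expelling a single noisy disease into a singleton cluster
removes a handful of large within-pairs from a small pool, nudging the
argmax one or two steps past the true number of groups. Averaging per
cluster and per cluster pair first (`pooling = "cluster"`, the default)
weights each cluster equally, is at least as literal a reading of
"average distance within and between partitions", and recovers planted
group counts reliably; the pair-pooled variant is kept as an option.
A "largest successive change" rule |Δ(k+1) − Δ(k)| was considered and
rejected: it cannot select `k_min` without an arbitrary convention for
Δ(k_min − 1), and any such convention either always or never prefers
the boundary, failing the obvious two-group case.

**Driver nodes.** The driver count `N − |maximum matching|` is the
well-defined quantity; the returned set is one valid choice among
matching tie-breaks. A perfect matching yields one driver by
convention. The test suite checks invariance of the count under node
permutations.

**Power-law exponents.** The discrete maximum-likelihood estimator at
`x_min = 1` (zeta normalization) is primary; the least-squares slope of
the log–log empirical pmf is reported alongside because the two can
differ noticeably on real degree data and the literature rarely states
which was used. Goodness of fit is out of scope.

**Betweenness.** Directed, unnormalized, endpoints excluded — the
standard definition. Only the ranking and the count of genes with
positive centrality are consumed downstream; both are invariant to
normalization.

**Fisher test.** The 2×2 test is one-sided ("greater") by default
because the over-representation hypothesis is directional; the exact
hypergeometric tail is evaluated in log space, so million-pair tables
are no problem. The two-sided variant is a flag.

**t-SNE.** The embedding is a QC/visualization aid only and never
feeds the classification. The package implements exact-gradient t-SNE
(perplexity calibration by bisection, early exaggeration, adaptive
gains) rather than the Barnes–Hut approximation: at the problem sizes
involved (hundreds to a few thousand diseases) the exact O(n²) gradient
is affordable and removes an approximation parameter. Perplexity is
shrunk automatically (with a message) when fewer than `3·perplexity+1`
rows are supplied.

**Pipeline intermediates** are written as annotated TSVs plus a JSON
manifest (version, seeds, input hashes). At the scales this package
targets, recomputation is cheaper than cache management, so no
content-hash resume layer is provided; reruns with the same
configuration are bit-identical.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` plants exactly the structures the pipeline consumes:

* a directed stochastic-block **core** made strongly connected by a
  cycle ordered by block (so strong connectivity costs only `n_blocks`
  cross-block edges and the planted communities stay detectable);
* **upstream** nodes with only core-pointing edges, **downstream**
  nodes fed only by the core, and **tendrils** pointing into the
  downstream fringe — by construction the bow-tie decomposition must
  recover these roles exactly, which the tests assert;
* **pathways** drawn from single blocks and **disease groups** drawn
  from group-specific blocks with per-gene substitution noise, so
  groups have distinct expected NIS profiles;
* a batch of diseases drawn wholly from downstream nodes to exercise
  the CATG-0 screen.

Default conditions: a 96-node core in 4 blocks (`p_in = 0.25`,
`p_out = 0.02`), 10 upstream / 12 downstream / 4 tendril nodes, 40
diseases in 4 groups of 10 with 6 genes each, 4 CATG-0 diseases, 12
pathways of 8 genes, substitution noise 0.1. These sizes keep a full
end-to-end run under a second while leaving each block large enough to
carry a distinct pathway signature; the noise level leaves roughly half
the diseases with at least one off-block gene, which is what makes the
recovery tests informative rather than trivial.

The generator does **not** emulate several properties of real
interaction data: scale-free degree distributions (block models are
Poisson-like), the extreme size asymmetry of a real bow tie (where the
core holds ~70% of nodes), incomplete and biased curation (ascertainment
toward well-studied genes), or gene sets overlapping across groups the
way real diseases share risk genes. Passing the planted-recovery tests
therefore demonstrates that the machinery is correct and that the
scoring separates genuinely distinct impact profiles — not that any
particular real dataset will yield clean categories.

## Degenerate inputs and tie-breaks

* Components of equal size: the one containing the lexicographically
  smallest gene wins.
* `k` candidates where a within- or between-mean is undefined are
  skipped and recorded.
* Diseases or pathways with no gene in the network are dropped by
  `restrict_gene_sets()` with their ids reported.
* Empty disease gene sets score 0 with a warning; pathways with no
  network gene raise an error.
* Zero-margin contingency tables return p = 1 with a note.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated
data: kernel oracles on 200 random digraphs of up to 12 nodes, layering
oracles on 100 digraphs of up to 10 nodes, betweenness oracles at 8
nodes, Louvain recovery on 60-node three-block graphs over 20 seeds,
and the full pipeline at the default synthetic conditions over 10
seeds. These sizes were chosen so that independent brute-force oracles
(explicit layer sets, path enumeration, factorial hypergeometrics)
remain exact and fast; all scoring code paths are size-independent.

## Known limitations

* Louvain is seed-dependent; module counts on real data are not
  reproducible across implementations, so module count is treated as
  data-specific rather than a correctness criterion.
* The bait→prey reading of interaction records is taken at face value;
  no attempt is made to distinguish experimental systems with genuine
  directional semantics from symmetric ones.
* Gene identifiers are opaque strings; no symbol/ID mapping is
  attempted.
* Refinement is declarative by design: the package applies dual
  memberships from a config file but does not automate the judgment
  that produces them.
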