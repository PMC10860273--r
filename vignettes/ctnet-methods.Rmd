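---
title: "Cell-type-specific interactome networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-specific interactome networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctnet)
options(ctnet.quiet = TRUE)
```

# Overview

`ctnet` starts from two inputs — a reference interactome (an undirected,
optionally weighted edge list over gene symbols) and a labeled single-cell
UMI count matrix — and carves one weighted network per cell type out of the
reference. On top of those networks it computes topological specificity,
pairwise network similarity, gene-set connectivity with a permutation null,
hypergeometric enrichment, random-walk prioritization, and a recovery-based
performance score against degree-matched null networks. This vignette
documents the statistical model behind each stage, the parameters that
matter, and the design decisions taken where the methodology left room.

# Transcriptional specificity

Counts are normalized as `log1p` of counts-per-10,000 (a fixed convention;
any depth-stable monotone normalization would serve). For gene $i$ and cell
type $c$, specificity is the Welch-style contrast

$$\mathrm{tranS}(i) = \frac{\bar{x}_{c}(i) - \bar{x}_{\mathrm{else}}(i)}
{\sqrt{s^2_{c}(i)/n_{c} + s^2_{\mathrm{else}}(i)/n_{\mathrm{else}}}},$$

where "else" pools all other cell types. Zero-variance degeneracies are
resolved conservatively: equal means give 0, and unequal means with two
zero variances give $\pm 50$ (a finite cap that preserves ordering without
infinities). Cell types need at least 2 cells; network construction
additionally requires `min_cells = 100` cells per cell type, the
conventional floor below which single-cell specificity estimates are too
unstable to support a network.

# Edge significance and the two network resolutions

Within each cell type, `tranS` is mapped through a rank-inverse-normal
transform, $z_i = \Phi^{-1}((r_i - 0.5)/G)$ with average ranks for ties, so
that the per-gene scores are exactly standard-normal quantiles under the
null of exchangeable genes. A reference edge $(i,j)$ whose endpoints were
both measured is scored by the Stouffer combination
$z_{ij} = (z_i + z_j)/\sqrt{2}$ with an upper-tail normal p-value,
BH-adjusted across all tested edges of that cell type.

The edge statistic is deliberately a closed-form combiner rather than a
subsampling ensemble: it is reproducible, cheap, and testable against its
analytic null. The combiner is a pluggable function argument
(`combiner =`), so alternatives (e.g. the minimum of the endpoint scores)
can be swapped in without touching the rest of the pipeline.

Two resolutions of the same construction are exposed:

* **Specific core** (`reconstruct_cell_type_network()`, `alpha_edge_q =
  0.05`): edges with `q <= 0.05` and `z_ij > 0`. Because the rank-INT caps
  $z_i$ at $\Phi^{-1}(1 - 0.5/G)$, the smallest attainable edge p-value is
  bounded (about $4\times10^{-7}$ at $G = 5000$) and BH across $\sim 2G$
  edges retains only edges between top-ranked genes. The core is therefore
  small by construction and is the right object for asking *which*
  interactions are distinctive of a cell type.
* **Propagation network** (`propagation_network()`, the same construction
  with the q filter released): every reference edge with a positively
  combined score, weighted by $z_{ij}$. This is the object for analyses
  that need a candidate pool at the scale of the interactome — gene-set
  connectivity deconvolution, random-walk prioritization, topology-based
  network comparison — while still tilting edge weights toward the cell
  type.

Edge weights are the combined z-scores themselves; both networks are always
subgraphs of the reference, and genes absent from the expression data
contribute no edges.

# Topological specificity

For a network with edge weights $w$, a gene's neighborhood strength is the
sum of its incident edge weights. The null model keeps the topology fixed
and uniformly reshuffles the multiset of edge weights; `topS` is the
z-score of the observed strength against that null. Two estimators are
implemented and serve as mutual oracles:

* Monte-Carlo: $\mu_R, \sigma_R$ over `n_shuffles` random permutations;
* closed form: sampling $d_i$ of the $M$ weights without replacement gives
  exactly $\mu_R(i) = d_i \bar{w}$ and
  $\sigma_R^2(i) = d_i s_w^2 (M - d_i)/(M - 1)$, with $\bar{w}, s_w^2$ the
  population mean and variance of the weights.

The closed form is the default (exact and O(M)). Degenerate nulls
($\sigma_R = 0$: all weights equal, or a node incident to every edge) give
`topS = 0` rather than NaN — a degenerate null carries no specificity
information. `topS` is invariant to global weight rescaling, and the
logistic transform `topS_transf` $= 1/(1+e^{-topS}) \in (0,1)$ equals 0.5
exactly at 0, which makes profiles comparable across networks of different
size. Percentile-rank comparison of `topS` against `tranS`
(`percentile_rank_log2fc()`, ranks ascending so the most specific gene has
percentile rank 1) flags genes whose network influence exceeds what their
expression alone suggests.

# Network similarity

Shared-edge similarity is the Spearman correlation of the weights the two
networks assign to edges present in **both** subgraphs induced by shared
nodes: a rank correlation needs paired observations, so edges present in
only one induced subgraph are excluded (a documented choice — the
alternative of imputing zeros would conflate missingness with weight).
Topology similarity is the Spearman correlation of `topS_transf` over
shared nodes, each score vector computed on its own network; because
Spearman is rank-invariant, this equals the correlation of raw `topS`.
Insufficient overlap (fewer than 3 shared edges/nodes) yields `NA`, never
0 — zero is a meaningful correlation. Matrix ordering/clustering is left to
plotting (`plot_similarity_matrix()`).

# Gene-set connectivity and deconvolution

Within-group connectivity of a set $S$ in a network with node set $V$ is

$$C(S) = \frac{\sum_{(i,j) \in E,\, i,j \in S \cap V} w_{ij}}{|S \cap V|}.$$

Per-gene normalization keeps the statistic comparable across sets with
different network coverage; `"sum"` and `"per_pair"` normalizations are
available as options. The null distribution is built by repeatedly drawing
uniform random node sets of size $|S \cap V|$ from the network — uniform,
not degree-matched, following the stated subsampling procedure; a
degree-biased null would be stricter for hub-rich sets and can be emulated
by the caller via the exposed machinery. The empirical p-value uses the
add-one correction $(1 + \#\{C_\mathrm{null} \ge C_\mathrm{obs}\})/(1 +
n_\mathrm{perm})$, so it is never 0. Scaled connectivity centers and scales
the per-cell-type permutation z-scores to mean 0, sd 1, giving the
deconvolution profile that assigns a signature to cell types; identical
profiles across cell types yield exactly the zero vector.

Calibration note: the permutation p-value is uniform only as far as the
statistic is continuous. On very sparse networks with small sets, $C = 0$
has appreciable probability and the p-value develops an atom at 1
(conservative, not anti-conservative). The calibration experiments
therefore use networks dense enough that random sets essentially always
contain internal edges.

Enrichment uses the upper-tail hypergeometric test
$P(X \ge k)$ with BH correction across the tested sets; the universe
defaults to the choice of the caller, and conditioning on the network's
node set is the recommended convention (measurable, connected genes).

# Random walk with restart and network performance

RWR iterates $p^{t+1} = (1-\gamma) W p^t + \gamma p^0$ with
column-normalized weighted adjacency $W$, restart probability
$\gamma = 0.5$, and an L1 convergence tolerance of $10^{-10}$. $p^0$ is
uniform over the seed genes present in the network (the neutral choice);
isolated nodes receive a unit self-loop purely for column-stochasticity and
can never receive probability from the seeds. Seeds are excluded from the
candidate ranking; ties break by gene symbol. The iteration is validated
against the direct solve of $(I - (1-\gamma)W)\,p = \gamma p^0$.

Network performance evaluates how well a network recovers a gene set:
members are repeatedly split into seeds (fraction 0.5, 10 repeats) and
held-out positives, and the ranking of non-seed genes is scored by AUPRC
(average-precision estimator) with all other non-seed genes as negatives.
The same splits are reused for the true network and each of `n_null = 20`
degree-preserving rewirings (double-edge swaps, 10 x |E| attempts, weights
re-permuted over the rewired edges), which removes split noise from the
paired comparison. Performance is the robust z-score of the true AUPRC
against the null ensemble (median/MAD with the 1.4826 consistency
constant); gain is the relative excess over the null median. An MAD of 0
leaves performance undefined while gain is still reported.

# The synthetic-data generator

The generator emulates the statistical structure the analyses assume, at
desk scale:

* **Reference**: preferential attachment (attachment 2, so mean degree
  about 4) over 5000 genes by default — scale-free-like, as curated
  interactomes are; a configuration-model alternative is available.
* **Counts**: negative binomial with variance $\mu + \phi\mu^2$
  ($\phi = 0.2$), gene baselines $\log$-normal
  ($\mu_0 = -2, \sigma_0 = 1$ on the natural-log scale), and per-cell
  lognormal depth factors (mean 10, sdlog 0.3) so specificity statistics
  are exercised against uneven library sizes.
* **Planted modules**: one connected subgraph of 20 genes per cell type
  (disjoint across cell types), grown breadth-first from a random node and
  co-upregulated with log2 fold change 2 — the recoverable ground truth for
  reconstruction, deconvolution and prioritization.
* **Cell-type programs** (`simulate_study()` condition: fraction 0.3 of
  non-module genes, half-normal log2FC with sd 0.5): each cell type
  additionally up-regulates a broad connected region of the reference.
  Real cell types differ in hundreds of genes whose products cluster on the
  interactome; without this background the reconstructed networks would
  contain little beyond the planted module itself, and permutation nulls
  over network nodes would degenerate. `generate_expression()` defaults to
  `program_frac = 0`, so the documented pure NB model (and the
  no-signal calibration behavior at log2FC 0) holds exactly unless the
  program is requested.
* **Panels** (`simulate_panel()`): module and program assignments are held
  fixed across contexts while baselines, depths and counts are resampled —
  emulating the same cell types profiled across cohorts, where
  same-cell-type networks should resemble each other more than
  different-cell-type networks do.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, zero inflation beyond NB zeros, gene–gene expression correlation
beyond the block structure of modules/programs, and any particular real
dataset. Passing recovery tests on these simulations demonstrates that the
statistics detect the structure they target at realistic noise levels; it
does not certify performance on real tissue atlases.

# Numerical choices and degenerate inputs

* Ranks use average ties, so an all-equal score vector maps to exactly 0
  and the degenerate all-equal-specificity input yields an empty network.
* Edge tables are canonicalized (lexicographic endpoint order), self-loops
  dropped and duplicates collapsed with logged counts; round-trip identity
  through the TSV/GraphML/MTX/GMT writers is tested.
* Undefined statistics are `NA` with a reason, never silent zeros: Spearman
  with < 3 pairs, connectivity with < 2 members in the network, performance
  with MAD 0.
* All stochastic stages take an explicit seed and restore the caller's RNG
  state; identical seeds give bit-identical results.
* Problem sizes used by the validation suite — 50 random graphs up to 200
  nodes for the RWR oracle, 10,000 reshuffles against the closed form on
  200-node networks, 200 + 500 random sets for calibration, a 5000-gene
  study with 3 x 500 cells for end-to-end recovery, and 20 rewiring trials
  for null self-consistency — were chosen to make the Monte-Carlo error
  small relative to the tested tolerances.

# Known limitations

* The edge-significance model is an analytic simplification of
  subsampling-ensemble approaches; absolute network sizes at a given
  `alpha_edge_q` are not comparable to those of other implementations
  (hence the two-resolution design).
* Uniform (not degree-matched) connectivity nulls favor hub-rich sets;
  interpret deconvolution profiles of hub-heavy signatures accordingly.
* Reference prior weights are carried through I/O but do not influence
  reconstruction; they are available to custom combiners.
* The permutation p-value is conservative on very sparse networks (atom at
  1), which costs power but never inflates false positives.
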