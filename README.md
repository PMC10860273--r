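# ctnet

Cell types rewire the molecular interaction networks they operate: a gene
that is broadly expressed can still play a sharply cell-type-specific role
through the partners it interacts with in that context. `ctnet` reconstructs
**cell-type-specific interactome networks** from labeled single-cell
expression data against a reference interactome (STRING-like edge lists),
and implements the downstream analyses such networks support:

* **Transcriptional specificity (`tranS`)** — a Welch-style contrast of a
  gene's normalized expression in one cell type versus all others:
  `tranS(i) = (x_ct(i) − x_else(i)) / sqrt(s²_ct(i)/n_ct + s²_else(i)/n_else)`.
* **Reference-guided reconstruction** — per cell type, each gene's `tranS`
  is mapped to a normal quantile by a rank-inverse-normal transform; a
  reference edge `(i, j)` is scored by the Stouffer combination
  `z_ij = (z_i + z_j)/√2`, converted to an upper-tail normal p-value and
  BH-adjusted across all tested edges. Edges with `q ≤ 0.05` and `z_ij > 0`
  form the sparse *specific core*; releasing the q filter yields the dense
  *propagation network* used for gene-set and random-walk analyses.
* **Topological specificity (`topS`)** — the z-score of a gene's
  neighborhood strength `w(i)` against a null that keeps the topology fixed
  and uniformly reshuffles edge weights:
  `topS(i) = (w(i) − μ_R(i)) / σ_R(i)`, with both a Monte-Carlo and an exact
  finite-population closed form; `topS_transf = 1/(1 + e^(−topS))`.
* **Network similarity** — Spearman correlation of shared-edge weights and
  of `topS_transf` over shared nodes; shared/unique node and edge ratios;
  multi-network intersection.
* **Gene-set connectivity deconvolution** — within-group connectivity
  `C(S) = Σ w(internal edges) / |S ∩ V|` with a permutation null built by
  repeatedly subsampling node sets of the same size from the network, plus
  scaled connectivity across cell types and hub/neighbor rankings.
* **Enrichment** — upper-tail hypergeometric tests with Benjamini–Hochberg
  correction.
* **Prioritization** — random walk with restart,
  `p^{t+1} = (1−γ) W p^t + γ p^0` (column-normalized `W`, γ = 0.5,
  L1 tolerance 1e-10), ranking candidate genes by stationary probability.
* **Network performance** — gene-set recovery AUPRC versus degree-matched
  rewired null networks: *performance* is the robust z-score
  `(AUPRC − median(null)) / (1.4826·MAD(null))`, *gain* is
  `(AUPRC − median(null)) / median(null)`.

A first-class synthetic-data module generates reference networks and
negative-binomial UMI counts with planted, connected cell-type modules, so
every stage is testable against a known ground truth without downloads.

All analysis functions return tibbles (or objects with `tidy()` / `glance()`
methods and `autoplot()` visualizations), so results chain with the pipe.

## Worked example

```r
library(ctnet)
options(ctnet.quiet = TRUE)

# a complete synthetic study: 5000-gene reference interactome, 3 cell types
# x 500 cells, one planted 20-gene connected module per cell type (log2FC 2)
study   <- simulate_study(seed = 7)
profile <- compute_transcriptional_specificity(study$expression)

# sparse specific core (q <= 0.05) and dense propagation network
core  <- reconstruct_cell_type_network(study$reference, profile, "ct_A")
dense <- propagation_network(study$reference, profile, "ct_A")
core
#> <ct_network> ct_A: 18 nodes, 17 edges (parent: synthetic_preferential_attachment)
dense
#> <ct_network> ct_A: 3681 nodes, 4827 edges (parent: synthetic_preferential_attachment)
```

The core retains the most specific interactions — dominated by the planted
module — while the dense network covers the measured interactome with
cell-type-tilted weights.

```r
glance(topological_specificity(dense))
#> # A tibble: 1 × 6
#>   cell_type mode        n_shuffles n_genes mean_topS max_topS
#>   <chr>     <chr>            <int>   <int>     <dbl>    <dbl>
#> 1 ct_A      closed_form         NA    3681    -0.157     12.7

# the planted module deconvolves to its cell type: observed connectivity
# 3.99 versus a null mean of 0.005 (permutation p = 1/1001)
mod <- study$truth$planted_modules$ct_A
connectivity_permutation_test(dense, mod, n_permutations = 1000, seed = 7)
#>   n_in_network observed null_mean null_sd   z empirical_p
#> 1           20     3.99   0.00524  0.0189 212    0.000999

# seed half the module, recover the held-out half by random walk
cand <- prioritize(dense, mod[1:10])
head(cand, 3)
#> # A tibble: 3 × 3
#>   gene   p_star  rank
#>   <chr>   <dbl> <int>
#> 1 g1424 0.0160      1
#> 2 g0985 0.00817     2
#> 3 g3255 0.00748     3
sum(mod[11:20] %in% head(cand$gene, 20))
#> [1] 9

performance_and_gain(dense, mod, n_null = 20, seed = 7)
#> <network_performance> ct_A: AUPRC = 0.6195, null median = 0.009403,
#>   performance = 202.8, gain = 64.89
```

Nine of the ten held-out module members appear among the top 20 candidates,
and the network's recovery AUPRC sits hundreds of robust standard deviations
above its degree-matched null ensemble.

## Vignette

`vignettes/ctnet-methods.Rmd` documents the statistical model, every tunable
parameter with its default and rationale, what the synthetic generator does
and does not emulate, and the package's design decisions and limitations.
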