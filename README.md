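# sirpredict

Exact expected SIR outbreak sizes on *all* small connected graphs, and
how well node centralities predict them.

## What this is for

In network epidemiology one usually ranks the nodes of a given contact
network by epidemic importance. This package targets the harder,
absolute question: across **every** nonisomorphic connected simple
undirected graph of a fixed size N (equally weighted), how well do the
raw values of standard centralities predict a node's expected outbreak
size Ω — the expected number of ever-infected nodes when the Markovian
SIR process (transmission rate β per S–I edge, recovery rate 1) is
seeded at that node? Answers at this level let importance thresholds
transfer between networks, which matters for small designed systems
such as farm-trade contact networks.

The package implements the whole pipeline:

- **graph ensemble** — exhaustive enumeration of nonisomorphic
  connected graphs (one canonical representative per isomorphism
  class), automorphism orbits, graph6 import/export bit-compatible
  with `geng` output for sizes you generate externally;
- **exact solver** — Ω for every seed and every β in one breadth-first
  unfolding of the SIR configuration tree with merging of identical
  configurations; exactness is cross-checked against an independent
  absorbing-Markov-chain linear solve and a compiled Gillespie
  simulator;
- **centralities** — degree, eigenvector, PageRank
  (`x = D(D−αA)⁻¹1`, α = 0.85), Katz (`x = (I−αA)⁻¹1`, α = 0.1),
  closeness, betweenness, coreness, plus edge density, all normalized
  to [0, 1] for cross-graph comparability;
- **learning protocol** — per-(combination, β) regression experiments:
  exact-duplicate removal, development/test split, grid-searched
  ten-fold cross-validation for random-forest and support-vector
  regressors, held-out R² = 1 − S_res/S_tot, learning-curve tuning of
  the development size, and permutation tests of significance;
- **prediction maps** — a trained two-feature SVR evaluated over the
  unit feature square with an achievability mask marking coordinates
  no real graph attains.

## A worked example

```r
library(sirpredict)

# the exhaustive six-node ensemble: 112 isomorphism classes
ens <- enumerate_connected_graphs(6)
length(ens)
#> [1] 112

# exact outbreak sizes for one graph, all seeds, nine betas
head(outbreak_table(ens[[100]]), 3)
#>   graph_id seed   beta    omega
#> 1     E`lo    1 0.0625 1.194290
#> 2     E`lo    1 0.1250 1.398025
#> 3     E`lo    1 0.2500 1.811982
# one solver call per automorphism orbit fills all equivalent seeds

# features + targets for the whole ensemble
records <- assemble_records(featurize(ens), solve_graphs(ens))
nrow(records)
#> [1] 672

# how well does degree alone predict omega at beta = 1/16?
v <- project_and_dedup(records, "degree", 1/16)
run_experiment(v, regression_config("forest"), seed = 7)
#> experiment: omega(beta = 0.0625) ~ degree [forest]
#>   rows 391, dev 293 (75%), test R^2 = 0.9860
#>   tuned: trees=20, leaf_fraction=0.003
```

At the smallest β an outbreak rarely travels past the seed's
neighbors, so degree alone explains ~99% of the variance in Ω.  At
larger β no single feature does well in the worst case (closeness is
the best, min-over-β R² ≈ 0.71 at N = 6), but pairing a
graph-size-sensitive measure with a normalized spectral centrality
(edge density + Katz, or density + PageRank) lifts the worst case to
≈ 0.89: the spectral value locates the node within its graph, density
captures the graph's overall capacity to sustain an outbreak.

```r
pt <- permutation_test(v, regression_config("forest"), n_permutations = 100, seed = 1)
pt$p_value
#> [1] 0.00990099   # = 1/101, the minimum attainable: real dependence
```

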