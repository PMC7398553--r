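---
title: "Exact SIR outbreak sizes on small graphs and their predictability from centralities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact SIR outbreak sizes on small graphs and their predictability from centralities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question this package answers

A central task of network epidemiology is identifying the nodes from
which an epidemic would spread furthest.  Most work ranks the nodes of
*one given* network and asks whether a centrality ranks them in the
same order as their epidemic importance.  This package addresses the
harder, absolute question: how well do the *raw values* of standard
node centralities predict the expected outbreak size of a node, across
*all* connected graphs of a given size at once?  The answer matters
whenever importance thresholds must transfer between networks — for
instance, small designed contact networks such as farm-trade systems,
where one wants "vaccinate every node more dangerous than x" to mean
the same thing in every network.

The package provides all the machinery end to end: the exhaustive
ensemble of nonisomorphic connected graphs, an exact solver for the
expected SIR outbreak size, the centrality suite with the
normalizations that make raw values comparable across graphs, the
supervised-learning protocol that quantifies predictability, and
prediction maps for inspecting the learned models.

## The epidemic model and its exact solution

The Markovian SIR model on an undirected graph has each node
susceptible (S), infectious (I), or recovered (R).  An infectious node
transmits along each of its S-neighbors' edges at rate $\beta$ and
recovers at rate $\nu$; time is measured in units of $1/\nu$, so
$\nu = 1$ and $\beta$ is the only parameter.  A *configuration* — one
state per node — fully determines the process.  If a configuration has
$M_{SI}$ edges joining an S node to an I node and $N_I$ infectious
nodes, the next event is an infection across one specific SI edge with
probability $\beta/(\beta M_{SI} + N_I)$ and the recovery of one
specific infectious node with probability $1/(\beta M_{SI} + N_I)$.

The *expected outbreak size* $\Omega$ for a seed node is the expected
number of ever-infected (equivalently, finally recovered) nodes when
the process starts with that node infectious and all others
susceptible.  Although the process is stochastic, $\Omega$ is a
deterministic quantity, and on small graphs it can be computed
*exactly*: the tree of configurations rooted at the seed is unfolded
breadth first, identical configurations reached along different paths
are merged by summing their probability mass (the process is
Markovian, so their futures coincide), and $\Omega$ is the
$N_R$-weighted mass over absorbing configurations.  Three
implementation details matter:

* **Merging is exhaustive.**  A configuration reached after $k$ events
  satisfies $k = (N_I + N_R - 1) + N_R$, so identical configurations
  always meet at the same BFS depth, and one hash map per depth
  suffices.  The solver asserts this invariant while it runs.
* **All transmission rates in one pass.**  Each configuration carries a
  per-$\beta$ probability vector, so the nine-value default grid
  ($\beta = 1/16, 1/8, \ldots, 16$, a geometric sequence with ratio 2)
  costs one traversal, not nine.
* **No pruning.**  Low-mass configurations are never dropped; the
  computation is exact up to double-precision round-off.  With at most
  $3^N$ configurations the accumulated float error stays many orders
  of magnitude below the $10^{-10}$ tolerance used when validating
  against the independent oracle (see below), so no exact-rational
  arithmetic is used.

```{r}
library(sirpredict)
expected_outbreak_size(igraph::make_full_graph(2), seed = 1, params = 1)
# closed form for the single edge: 1 + beta/(beta + 1) = 1.5 at beta = 1
```

Two independent oracles guard the solver.  `markov_oracle()` computes
$\Omega$ by a completely different route — the full $3^N$-state
absorbing Markov chain and one sparse linear solve — and must agree to
$10^{-10}$.  `gillespie_estimate()` is an event-driven Monte-Carlo
simulation (compiled, sharing nothing with the solver but the rate
definitions) and must agree to within three standard errors.

Seeds in the same automorphism orbit give identical $\Omega$, so
`outbreak_table()` solves once per orbit of `node_orbits()` and copies
the result — the same deduplication that makes the exhaustive-ensemble
computation tractable.

## The graph ensemble

`enumerate_connected_graphs(n)` generates exactly one representative
per isomorphism class of the connected simple undirected graphs on `n`
nodes (112 classes at $n = 6$; 853 at $n = 7$), weighted equally.
Enumeration proceeds by vertex extension — every graph on $n$ nodes
contains one on $n-1$, so attaching a new vertex to every subset of an
exhaustive $(n-1)$-set and deduplicating by canonical label is
exhaustive — with the canonical label (BLISS canonical permutation,
encoded as graph6) doubling as a stable `graph_id`.  The ensemble
order is deterministic (sorted by canonical label), so a run seed
fully reproduces every downstream split.  In-process enumeration is
intended for $n \le 8$; larger ensembles are generated externally
(e.g. with nauty's `geng`) and imported with `read_graph6()`, which is
bit-compatible with that tooling.  Node indices are 1-based
throughout, as everywhere in R.

## The predictor features

Eight features, all mapped to $[0,1]$ so that raw values are
comparable across graphs:

| feature | definition | normalization |
|---|---|---|
| degree | $\deg(i)$ | $/(N-1)$ |
| eigenvector | principal eigenvector of $A$ | 2-norm $= 1$ |
| PageRank | $x = D(D-\alpha A)^{-1}\mathbf 1$, $\alpha = 0.85$ | sum $= 1$ |
| Katz | $x = (I-\alpha A)^{-1}\mathbf 1$, $\alpha = 0.1$ | 2-norm $= 1$ |
| closeness | $(N-1)/\sum_j d_{ij}$ | already in $(0,1]$ |
| betweenness | pair-dependency sum | $/\binom{N-1}{2}$ |
| coreness | largest $k$ with $i$ in a $k$-core | $/(N-1)$ |
| edge density | $M/N$ (half the mean degree) | $/\frac{N-1}{2}$ |

Design choices worth stating:

* **PageRank is the matrix-resolvent form above**, solved literally,
  not the teleportation random-surfer recursion; the two differ in
  general.  The resolvent form is what the per-graph sum
  normalization is applied to.
* **Betweenness and coreness are scaled by their theoretical maxima**
  ($\binom{N-1}{2}$, attained by a star center, and $N-1$), not
  per-graph maxima.  Per-graph scaling would force a value of 1.0 in
  every graph and destroy exactly the cross-graph comparability of raw
  values that the analysis studies.
* **Katz attenuation** $\alpha = 0.1$ is checked against $1/\lambda_1$
  for every graph processed (it is safely below it for all graphs
  considered here); the computation errors out rather than silently
  diverging.
* On a connected *regular* graph the degree, spectral and coreness
  features are provably constant across nodes; closeness and
  betweenness are constant only on vertex-transitive graphs, and
  regular non-vertex-transitive graphs exist from $n = 7$ on.  The
  test suite checks constancy for the provably constant subset.

## From features to predictability

`assemble_records()` joins features to exact outbreak sizes: one
record per (graph, node) with eight predictors and one
$\Omega(\beta)$ per grid value.  `project_and_dedup()` selects a
feature combination and one $\beta$ and removes *exact duplicates* —
rows identical on selected features and target, which arise chiefly
from automorphically equivalent nodes — so no test row can be
identical to a training row.  Rows with equal features but different
targets are kept: they are irreducible prediction error and part of
what the analysis measures.  Duplicate detection keys on values
rounded to 12 significant digits, because orbit-equivalent nodes agree
only up to linear-algebra round-off ($\sim 10^{-16}$) while genuinely
distinct rows differ at far coarser scales.

`run_experiment()` then: splits the deduplicated view into development
and test parts (75% development by default at these data sizes); runs
a grid search with ten-fold cross-validation on the development part —
random forests over trees $\in \{5,10,15,20\}$ and minimum leaf
fractions $10^{-2} \ldots 10^{-4}$, or support-vector regression over
$\{$linear, RBF$\}$ kernels and $C \in \{0.1,1,10,100\}$ with
$\varepsilon = 0.01$ and $\gamma = 1/(d \cdot \mathrm{var}(X))$; ties
broken toward the simpler model — refits the winner on all development
data and reports held-out $R^2 = 1 - S_{\mathrm{res}}/S_{\mathrm{tot}}$.
Everything is reproducible from one seed; the forest path is
bit-identical across repeats.

The development size can itself be tuned with `tune_dev_size()`: ten
candidate sizes on a linear scale, each cross-validated, choosing the
smallest size whose validation score is within 0.005 of its maximum
and within 0.02 of the training score.  The learning curve is traced
with a reference forest using a fixed leaf fraction of 0.03 — heavier
smoothing than the tuning grid — because in-sample training scores of
fine-leaved forests are memorization-inflated and would never close
the 0.02 gap regardless of data size.  On the six-node ensemble the
curve keeps improving almost to the end: the chosen development
fraction lands near 90%, consistent with small ensembles being
data-limited.

`permutation_test()` guards against spurious scores: the
cross-validated score of the real data is compared with scores after
permuting the target, and $p = (1 + \#\{\mathrm{permuted} \ge
\mathrm{real}\})/(1 + n_{\mathrm{perm}})$, whose minimum attainable
value $1/101$ at the default 100 permutations is what real
feature–target dependence produces.

`sweep_experiments()` runs the grid of (combination, $\beta$) cells
and summarizes each combination by its *minimum* $R^2$ across
$\beta$ — the worst-case guarantee a practitioner would care about.

## What the desk-scale analysis shows

The bundled tests and the acceptance script work on the exhaustive
$n = 6$ ensemble (672 records; a deliberate choice that keeps the full
suite in minutes — the identical code path scales to larger $n$, at
the cost of compute that grows with the ~$2^{\binom{n}{2}}$ class
counts).  The qualitative structure of the full-scale analysis
reproduces there:

* degree is the most predictive single feature at the smallest
  $\beta$, where an outbreak rarely travels beyond the seed's
  neighbors;
* closeness is the best single feature in worst case across $\beta$;
* pairing a graph-size-sensitive measure with a normalized spectral
  centrality (density + Katz, density + PageRank) lifts the worst-case
  $R^2$ far above any single feature — the spectral value pins the
  node's position inside its graph while density pins the graph's
  propensity to sustain an outbreak;
* predictability of the best combinations declines at the largest
  $\beta$.

Numbers for these statements are computed, not quoted: run
`scripts/acceptance.R` (see the README) or the test suite.

## Prediction maps

`map_series()`/`build_map()` evaluate a trained two-feature
support-vector model (the smooth, interpretable regressor) on a
$100 \times 100$ grid over the unit feature square.  Graphs only
attain a sparse pattern of feature coordinates, so each cell carries
an attainability flag — a cell is attainable iff at least one observed
data point falls in it, the most literal reading of "devoid of data
points".  The mask depends only on the deterministic dataset, not the
model seed.  For size comparisons the mapped quantity is the outbreak
fraction $\Omega/N$.

## What the synthetic conditions do and do not show

The ensemble *is* the study population — every connected graph of the
given size, equally weighted — so there is no sampling error on the
graph side, and the exact solver removes all simulation noise from the
targets.  What desk scale does not show: the headline figures of a
full-scale ($N = 10$, 11.7 million classes) analysis, which need
external enumeration and long compute on exactly this code path; and
any claim about *large* graphs, where closeness in particular is known
to lose discriminating power.  Stochastic elements (splits,
cross-validation folds, forests) are fully seed-controlled; forest
results are bit-reproducible, support-vector results reproducible to
numerical tolerance.

## Known limitations

* In-process enumeration is practical to $n \approx 8$; beyond that,
  import externally generated graph6 sets.
* The exact solver's configuration space grows like $3^N$ in the worst
  case; $N = 10$ is feasible per graph but multi-day over the whole
  ensemble, as in the original full-scale analysis.
* `markov_oracle()` is deliberately capped at $N \le 6$ (dense state
  enumeration); it is a validation tool, not a production solver.
* Random forests carry a small negative $R^2$ bias on pure-noise
  targets at these leaf sizes; the permutation test, not the raw
  score, is the significance instrument.
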