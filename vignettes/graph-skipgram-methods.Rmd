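---
title: "Structure-aware skip-gram embedding of networks: models and methods"
author: "gskipgram maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware skip-gram embedding of networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gskipgram)
```

# The problem

Many biological networks — protein–protein interaction graphs chief among
them — come with no node attributes: all the information is in the wiring.
Unsupervised node embedding maps each node to a dense vector
$f : V \to \mathbb{R}^d$ so that downstream tasks (functional
classification, module detection, interaction prediction) can run on
ordinary feature matrices. The random-walk skip-gram family (DeepWalk,
node2vec) does this by treating truncated random walks as sentences and
maximizing

$$\max_f \sum_{u \in V} \log \Pr\left(N_S(u) \mid f(u)\right),$$

where $N_S(u)$ is the multiset of nodes co-occurring with $u$ within a
window of the walks. This package implements that baseline and a
structure-modulated variant in which the co-occurrence probability of a
pair is reweighted by explicit graph structure — node degrees and
shortest-path distances — plus a selective fusion step for the two vector
sets skip-gram learns per node.

# The model

## Two embeddings per node

Skip-gram with negative sampling learns an *input* embedding $f$ (used
when a node is the walk center) and an *output* embedding $f'$ (used when
it is a context or noise draw). Training starts from
$f \sim U[-0.5/d, 0.5/d]$ and $f' = 0$; because the two matrices converge
toward each other, the asymmetric start accelerates early training. Both
matrices are first-class citizens here (`EmbeddingSet` keeps the pair),
because the fusion step below needs them.

## The structure weight

For a center $u$ and a reachable context $n$, the structure function is

$$W(n,u) \;=\; w \cdot \mathrm{clamp}\!\left(\frac{D_u}{D_n};\, 1, 1.1\right)
 \;+\; (1-w)\left(2 - \frac{2\,P_{un}}{p}\right)^{a}
 \;\;\left[+\; w' \cdot \mathrm{weight}(u,n)\right],$$

with $D$ the degree vector, $P$ the shortest-path matrix, and the
bracketed term only on weighted graphs. The first term nudges
co-occurrence up when a hub samples a lower-degree neighbour (the ratio is
clamped into $[1, 1.1]$, so it acts as a bounded bonus, never a penalty);
the second decays with distance and vanishes as $P_{un} \to p$. The base
of the distance term is floored at zero before the exponent is applied, so
fractional exponents ($a = 0.5$ is useful when the distance distribution
is very concentrated) never see a negative base. A reachability indicator
$L(n,u) \in \{0,1\}$ — zero for self pairs and cross-component pairs —
enters as an exponent $W^L$, which makes the multiplier exactly 1 wherever
$W$ is undefined. Unreachable distances are kept as `Inf`, never 0: a
zero would collide with the self-distance $P_{uu} = 0$, and both cases
map to $L = 0$ anyway.

The scored co-occurrence is

$$A(f'(n), f(u)) = \mathrm{clip}\left(\sigma\!\left(f'(n)^\top f(u)\right)
  \cdot W(n,u)^{L}\,,\; -1,\; 1\right).$$

We apply $W$ *outside* the sigmoid and then clip: the clipping rule only
has content if $A$ can exceed 1, which the sigmoid alone cannot. The
inside-the-sigmoid reading ($\sigma(s \cdot W^L)$) is available via
`trainConfig(wInside = TRUE)` for comparison. The lower clip at $-1$ is
retained for fidelity to the scoring rule even though $A \ge 0$ under this
reading makes it unreachable.

## Updates

Training iterates over (center, context) pairs drawn from the walk corpus
with a word2vec-style shrinking window (the effective window is uniform on
$\{1..m\}$ per position). Each positive pair is followed by $k$ draws from
the unigram noise distribution (corpus frequency to the power 0.75),
resampled when a draw equals the center; duplicates are allowed. Per pair:

* vanilla mode: $g = (\text{label} - \sigma(s)) \cdot \alpha$ with
  $s = f'(n)^\top f(u)$. This is the exact gradient of
  $\log \sigma(s)$ (label 1) and $\log \sigma(-s)$ (label 0), which the
  finite-difference tests verify. The sign flip of the negative term
  lives in the objective; the update formula is the same expression for
  both labels.
* graph mode: $g = (\text{label} - A) \cdot \alpha$ with the clipped $A$
  above, and both row updates (context row and the center-row error
  accumulator) additionally scaled by $W^L$ — $W$ is treated as a
  constant multiplier of the co-occurrence probability, not
  differentiated through. With every multiplier equal to 1 this reduces
  *bit-for-bit* to vanilla mode under the same seed, a property the test
  suite asserts with `identical()`.

The error accumulator collects $f'(n) \cdot g \cdot W^L$ using the context
row *before* that row is updated, and the center row $f(u)$ is applied
once per positive pair after its negatives. The learning rate decays
linearly from $\alpha_0$ (default 0.025) to $\alpha_0 \cdot 10^{-4}$ over
the pair budget. Since $0 \le A \le 1$ under the chosen reading,
$|g| \le \alpha$ at every step, which keeps training finite without
gradient clipping. The inner loop is compiled (Rcpp) and mirrors the
exported reference `pairUpdate()`; a test holds the two in lockstep. It
draws from R's RNG, so one `set.seed()` makes single-threaded runs
bit-reproducible; asynchronous multi-threaded updating is deliberately not
implemented, trading speed for exact reproducibility.

## Fioepn: selective input/output fusion

After training, most nodes' $f$ and $f'$ rows roughly agree; the nodes
where they disagree are the ones whose input embedding is least supported
by how the rest of the network sees them. Fioepn scores each node by the
similarity of its two rows, takes the score at sorted position
$\lfloor \text{ratio} \cdot |V| \rfloor$ (0-based) as the threshold, and
replaces $f$ by $(f + f')/2$ for nodes scoring *strictly below* it; all
other rows are returned unchanged. Ratio 0 is therefore the identity, and
threshold ties are never fused. Cosine similarity is the default — it is
invariant to the different scales of the randomly-initialized $f$ and the
zero-initialized $f'$ — with the raw dot product selectable
(`similarity = "dot"`) since the procedure is equally well-defined either
way. Fusion is applied once; re-fusing re-averages and is not idempotent.

# Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `w` | degree/distance mixing weight | 0.8 | in $(0,1)$; larger favours the degree term |
| `distanceScale` ($p$) | distance decay scale | auto | chosen as max finite distance + 1, so the decay term stays positive |
| `a` | distance-term exponent | 1 | fractional values spread a concentrated distance distribution |
| `wPrime` ($w'$) | edge-weight coefficient | 0 | only on weighted graphs; added on top, not renormalized |
| `dim` ($d$) | embedding dimension | 128 | 2 in the karate demonstration for direct visualisation |
| `window` ($m$) | context window | 10 | effective window shrinks uniformly per position |
| `walksPerNode` ($r$) / `walkLength` ($t$) | corpus size | 80 / 10 | karate demo uses 40 / 40 |
| `negatives` ($k$) | noise draws per pair | 5 | 1 in the karate demo |
| `alpha0` | initial learning rate | 0.025 | linear decay to $10^{-4} \alpha_0$ |
| fusion `ratio` | fraction of nodes eligible to fuse | 0.10 | 0.5 in the karate fusion experiment |

The degree-ratio clamp $[1, 1.1]$ is exposed
(`degreeRatioBounds`) but rarely worth changing: it is a bounded
correction, and widening it makes the degree term dominate.

# What the synthetic generator does and does not emulate

`sbmGraph()` draws a stochastic block model: independent edges with
probability `pIn` within planted blocks and `pOut` between them. This
captures the community structure that makes PPI-like graphs interesting
for embedding — dense modules, sparse cross-talk — and gives ground-truth
labels for scoring recovery (within- versus between-block cosine
similarity, Calinski–Harabasz against planted labels, link prediction
above chance). It does **not** produce heavy-tailed degree sequences:
within a block, degrees are binomial and tightly concentrated. Passing
the recovery tests therefore demonstrates community recovery, not
robustness to scale-free hubs; the karate network (degrees 1–17 over 34
nodes) covers the hub regime at small scale, and nothing in the test
suite should be read as evidence about graphs with millions of nodes.

# Numerical and design choices

* **Node order**: identifiers are strings; when every identifier parses
  as a number the row order is numeric, otherwise lexicographic. All
  matrices (embeddings, $P$, multipliers) share this order.
* **Duplicate edges** collapse to the first occurrence with a warning;
  self-loops are dropped with a message. Both choices keep the graph
  simple, which the degree and distance definitions assume.
* **Dense $P$**: the shortest-path matrix is computed dense (igraph's
  BFS/Dijkstra). This package targets desk-scale graphs (tens to a few
  thousand nodes); `computeShortestPaths(g, sources=)` exists for
  sampling rows of larger graphs, and
  `estimateDistanceDistribution()` chooses $p$ from sampled sources
  without materializing the matrix.
* **Threshold index convention** in Fioepn: `sorted[floor(ratio * |V|)]`
  with 0-based indexing plus strict inequality. The boundary cases
  (ratio 0 fuses nothing; ratio 1 fuses everything strictly below the
  maximum score) are asserted exactly in the tests.
* **Modularity classes** come from greedy (agglomerative) modularity
  maximization, relabelled deterministically by each community's first
  member so "class 3" means the same thing on every run. On the karate
  network this yields 3 classes (sizes 8/17/9).
* **Classifiers** in the evaluation module are ridge-penalized logistic
  regressions (`glmnet`, $\lambda = 1/n_{\text{train}}$, matching an L2
  strength of 1 in the $C$-parameterization), one-vs-rest for
  multi-label scoring with the known-label-count top-$k$ assignment
  rule, and a single binary model over edge features for link
  prediction. Link-prediction positives are the removed edges (test
  side) and an equal-size sample of residual edges (train side);
  negatives are sampled non-edges, matched in count; removals that would
  disconnect the residual graph are rejected.

# Problem sizes used in the checks

The packaged experiments are sized for a desk run: the 34-node karate
network with $r = 40$, $t = 40$, $m = 5$, $k = 1$, $d = 2$ over 10 seeds
(roughly 300k pair updates per run), and 120-node four-block SBMs
($p_{\text{in}} = 0.25$, $p_{\text{out}} = 0.02$) with $d = 16$,
$r = 10$, $t = 20$, $m = 5$, $k = 5$ over 10 seeds. These sizes exercise
every code path; the same functions run unchanged on larger edge lists.

# Known limitations

* The karate clustering comparison depends on the class partition. The
  greedy-modularity 3-class partition used here is deterministic and
  reproducible, but per-class quantities (for example the third class's
  within-group sum of squares) are not comparable across different
  partitions of the same graph, and published per-class figures that used
  a different (unprinted) 4-class numbering can only be matched
  approximately. The package reports what it computes; the direction of
  the effects (graph mode improves CH; fusion tightens at least one
  class) is the stable part, and the per-seed spread of the 2-d karate
  runs is large.
* Training is single-threaded by design; on large corpora the walk and
  pair generation (plain R) dominate before the compiled SGD loop does.
* The full softmax denominator of the co-occurrence model is never
  materialized — negative sampling stands in for it — so reported scores
  are not normalized probabilities.
* Whether the structure weight should also modulate negative pairs is
  settled here by applying $W^L$ to both terms of the objective (the
  same scored $A$ everywhere); negatives drawn far from the center get
  small distance terms, which slightly dampens repulsion. The reduction
  and gradient tests pin this choice down.

```{r session}
sessionInfo()
```
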