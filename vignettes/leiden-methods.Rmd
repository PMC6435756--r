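---
title: "Community detection with connectivity guarantees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community detection with connectivity guarantees: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leidenr)
```

## The problem and the two objectives

Given an undirected graph with positive edge weights, community detection
seeks a partition of the nodes into internally dense groups. `leidenr`
optimises one of two quality functions. Modularity compares each community's
internal weight $e_c$ with the configuration-model expectation,

$$\mathcal{H} = \frac{1}{2m}\sum_c\left(2e_c - \gamma\frac{K_c^2}{2m}\right),$$

where $K_c$ is the summed strength of the community's nodes, $m$ the total
edge weight and $\gamma > 0$ the resolution. The Constant Potts Model (CPM)
replaces the degree-based null by a fixed density threshold,

$$\mathcal{H} = \sum_c\left[e_c - \gamma\,\frac{n_c(n_c-1)}{2}\right],$$

with $n_c$ the summed node sizes (1 for raw networks, so the penalty is the
binomial pair count). The pair count is written on summed sizes rather than
member counts because that is the unique form preserved exactly by
aggregation, which the multilevel recursion requires. For the same reason a
self-loop of weight $w$ contributes $2w$ to its node's strength and $w$ to
$e_c$ and to $m$: with these conventions collapsing any community into a
single aggregate node with a self-loop changes neither objective, to machine
precision, and the all-in-one partition scores exactly zero modularity at
$\gamma = 1$.

Both algorithms make greedy decisions from the same "score" algebra: the
quality change of moving node $v$ into community $c$ is a positive constant
times

$$w(v, c\setminus v) \;-\; \gamma_{\mathrm{eff}}\, a_v\,(A_c - [v \in c]\,a_v),$$

with $a$ = node size and $\gamma_{\mathrm{eff}} = \gamma$ for CPM, $a$ =
strength and $\gamma_{\mathrm{eff}} = \gamma/(2m)$ for modularity. All move,
merge and subset deltas in the package reduce to differences of this form,
which is what makes the two objectives share one implementation and what the
test suite verifies against full recomputation at $10^{-9}$ tolerance.

## The algorithms

**Louvain** alternates (1) local moving — sweep all nodes in a fresh random
order, greedily moving each to the best community including a fresh empty
one, until a sweep makes no move — and (2) aggregation of the resulting
partition, restarting the aggregate level from singletons. It guarantees
γ-separation (no two communities merge profitably) and, at a stable
iteration, node optimality. It does *not* guarantee connected communities: a
node that bridged two parts of its community can move away, and no later
single-node move repairs the orphaned community. `make_bridge_fixture()`
constructs a certified minimal instance of this failure.

**Leiden** differs in both phases and adds a third:

1. *Fast local move.* A queue holds all nodes in random order; after a move,
   only neighbours outside the node's new community re-enter the queue. Our
   implementation adds a verification sweep once the queue drains: moving a
   node into community $c$ changes $A_c$ and can create an improving move for
   a node adjacent to $c$ whose own neighbourhood never changed, so the pure
   queue discipline alone does not strictly imply node optimality. The sweep
   re-checks every node (reseeding the queue on any hit), making the
   node-optimality post-condition unconditional at the cost of one $O(n)$
   pass.
2. *Refinement.* Starting from singletons inside each community $S$ of the
   partition, still-singleton nodes that are well connected within $S$ may
   merge into a refined community $C \subseteq S$ that is itself well
   connected, where well-connectedness of a part $X$ is the cut bound
   $E(X, S\setminus X) \ge \gamma_{\mathrm{eff}}\, a_X (a_S - a_X)$. Among
   candidate targets with non-negative quality change (staying put included),
   one is drawn with probability $\propto \exp(\Delta/\theta)$;
   quality-decreasing mergers are excluded, so refinement never lowers the
   quality. As $\theta \to 0$ the draw concentrates on the greedy argmax; the
   suite verifies the selection distribution on a fixture whose outcome
   probabilities are derived by enumerating visit orders.
3. *Aggregation on the refined partition*, with each refined community
   initially assigned to its community in the unrefined partition. Because a
   community can enter the next level as several aggregate nodes, later
   levels can split it — exactly the repair Louvain lacks.

Refined communities are connected by construction (a merge needs a positive
connection), every output community is a union of refined communities kept
together only by improving aggregate moves, so Leiden's output communities
are always connected. The level recursion ends when every community is a
single aggregate node, which with node optimality yields γ-separation. In
the rare corner where refinement returns all singletons while the partition
is still coarser (possible when all available mergers have exactly zero
gain and the $\theta$-draw declines them), refinement is retried a bounded
number of times; node optimality guarantees some pair with
$w_{uv} \ge \gamma_{\mathrm{eff}} a_u a_v$ exists in every multi-node
community, so the stagnation is transient.

## Tunable parameters

- `gamma` (resolution, default 1): granularity of the partition; under CPM
  it is interpretable as an edge-density threshold in units of weight per
  node-size pair.
- `theta` (refinement randomness, default 0.01, sane range roughly
  0.0005–0.1): temperature of the merge draw. Smaller values are nearly
  greedy; larger values explore more of the partition space per iteration.
- `seed`: every random order and draw derives from it; runs are
  bit-reproducible per seed.
- `max_iterations` (default 10) and `stop_policy`: `until_stable` stops at
  the first unchanged iteration, `until_converged` additionally requires
  `converged_patience` (default 10) consecutive unchanged iterations plus
  passing node-optimality and γ-separation checks. The patience exists
  because convergence of the randomized refinement is asymptotic: one
  unchanged iteration is weak evidence that no alternative split remains.
- Improvement threshold: a move must beat staying by more than $10^{-12}$
  (absolute); ties keep the current community, then prefer the lowest
  community label, making runs deterministic per seed and immune to
  rounding-noise move loops.

## The synthetic benchmark

`generate_benchmark()` plants equal-size communities (defaults: community
size 50, average degree 10) and places `round(n * avg_degree / 2)` distinct
edges; an edge is inter-community with probability μ (two distinct
communities chosen uniformly, a uniform endpoint in each) and intra-community
otherwise. The number of inter-community edges is drawn first
(binomially), then each type is filled by rejection sampling of distinct
edges. Drawing the type count first matters: resampling rejected duplicates
with a fresh type would skew the realized mixing upward, because the
intra-community pair pool is far smaller and collides more often.

`resolution_from_mu()` converts μ into a CPM resolution. With expected
densities $p_{\mathrm{in}} = (1-\mu)\langle k\rangle/(c-1)$ and
$p_{\mathrm{out}} = \mu\langle k\rangle/(n-c)$ typically orders of magnitude
apart, the geometric mean $\sqrt{p_{\mathrm{in}} p_{\mathrm{out}}}$ is used:
the midpoint of the admissible interval on a log scale, maximizing the ratio
margin against both failure modes (splitting a planted community becomes
profitable as γ approaches $p_{\mathrm{in}}$; merging two of them as γ
approaches $p_{\mathrm{out}}$). The arithmetic midpoint is a poor choice
here: at $n = 1000$, $c = 50$, $\langle k\rangle = 10$, $\mu = 0.2$ it lies
close enough to $p_{\mathrm{in}}$ that density fluctuations make splitting
planted communities strictly profitable, and even an exact CPM optimizer
returns a finer partition than the planted one. At $\mu = 0$ the rule
returns $p_{\mathrm{in}}/2$ (any value below $p_{\mathrm{in}}$ detects the
partition).

What the generator does *not* emulate: heavy-tailed degree and community-size
distributions, overlapping communities, weights, and local clustering beyond
what independent edge placement produces. Passing the benchmark therefore
shows correct optimisation behaviour under a clean planted model, not
performance on empirical networks, whose richer structure the original
experiments found to be harder.

Two caveats on "exact recovery", both measured by the test suite rather than
assumed. First, the planted partition is not always the CPM optimum: with
Poisson-like degrees a node occasionally has strictly more links to a
foreign community than to its own, and the optimizer correctly prefers the
(different) optimum; at μ = 0.2 this caps exact-match recovery around
60–90% of seeds depending on the draw. Second, exact ties
($\Delta = 0$ plateaus) can trap a node one γ-unit of quality away from the
planted assignment. Neither failure is a search defect — in every such seed
the found partition is node optimal, γ-separated, and its quality is within
a fraction of a percent of (usually above) the planted partition's.

## The audit

`audit_partition()` re-clusters each community's own subnetwork with Leiden
until a stable iteration and flags the community as *badly connected* if the
subnetwork splits (disconnected communities are the extreme case and are
counted among them). For modularity, the subnetwork keeps the full graph's
$2m$ and the original node strengths, so a split found on the subnetwork is
guaranteed to raise the full network's modularity — the audit asserts this
gain is positive whenever it flags. The audit is a lower bound: a community
it does not split is not thereby certified well connected.

## Guarantee checkers and their scope

γ-separation, connectivity and node optimality are checked exactly in
polynomial time. Subpartition γ-density follows its recursive definition
(some bipartition whose parts are mutually well connected, inseparable from
the community, and themselves dense); uniform γ-density quantifies over all
bipartitions; subset optimality over all subsets and all target communities.
These three enumerate exponentially many cases and are capped at
`max_exhaustive = 12` nodes per community, returning `NA` ("not checkable",
distinct from `FALSE`) above the cap. They are meant for fixtures and small
audits, not production-size communities.

## Known limitations

- *Asymptotic guarantees are asymptotic.* Subset optimality at convergence
  holds almost surely only in the iteration limit. With $\theta = 0.01$, a
  refinement draw that declines a merger with gain $\Delta$ has probability
  $e^{-\Delta/\theta}$; when exposing an improving subset move requires
  declining a $\Delta \approx 0.26$ merger, the escape probability is
  $\sim 10^{-11}$ per iteration and no practical run will take it. On small
  random graphs this leaves roughly 1 in 50 converged runs short of
  exhaustive subset optimality — a property of the algorithm itself, not of
  this implementation, and the acceptance script reports the measured rate.
- Directed, bipartite and streaming graphs are out of scope; unweighted
  input is handled as weight-1 edges.
- The exhaustive checkers' 12-node cap means large communities are never
  certified subpartition-dense, uniformly dense, or subset optimal.

## Problem sizes used by the automated checks

The suite exercises: the planted benchmark at $n = 1000$ (10 seeds, two
iterations); connectivity over 100 random graphs with $n \le 300$ at mixed
densities × 5 seeds × 3 iterations; the guarantee hierarchy on 25 mid-size
graphs (stable) and 50 graphs with $n \le 10$ (converged, exhaustive
checkers); 1000 randomized delta cases against full recomputation; and
10-seed generator moment checks. These sizes were chosen so the full suite
exercises every guarantee at exhaustively verifiable scales.
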