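---
title: "Methods: greedy cophylogeny reconstruction by cherry collapse"
author: "cophycollapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: greedy cophylogeny reconstruction by cherry collapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophycollapse)
```

## The problem

A tanglegram couples a rooted bifurcating host phylogeny $H$, a parasite
phylogeny $P$ and a map $\varphi$ sending each parasite leaf to the single
host leaf it inhabits.  An event-based reconciliation ("cophylogeny
mapping") explains $P$ inside $H$ using four events: **codivergence**
(host and parasite diverge together), **duplication** (the parasite
diverges independently, both daughters tracking the same host lineage),
**host switch** (an independent divergence where one daughter jumps to a
contemporaneous host lineage) and **loss** (failure to diverge with the
host, extinction, or a sampling artefact).  Under the default *Jungle*
weights $(w_C, w_D, w_S, w_L) = (0, 1, 2, 1)$ the goal is a minimum-cost
mapping; finding one is NP-hard in general, and even polynomial-time
relaxations that ignore the relative order of host divergences can return
*time-inconsistent* mappings, in which a switch jumps between host edges
that never coexisted — biologically infeasible histories.

This package implements the linear-time alternative: fix a **node
ordering** — unique integer depths $d(\cdot)$ on host internal nodes, root
0, children strictly deeper, all leaves at the common depth
$n_{\text{int}}$ — and reconstruct greedily by collapsing **cherries**
(pairs of leaves sharing a parent).  An outer genetic algorithm searches
the exponential space of orderings.

## Time model

The edge from $u$ to its child $v$ is *alive* during the half-open integer
interval $[d(u), d(v))$.  Every event carries an integer time index: a
codivergence at host node $v$ happens at $d(v)$; duplications and switches
happen on edges, inside the edge's interval.  A switch is time-consistent
iff its take-off and landing edges are both alive at its time index.
Because path edges partition $[0, d(\cdot))$, two distinct edges alive at
the same instant can never be ancestor-related, so the integer check is
complete.  `audit_time_consistency()` verifies exactly this, plus
parent-before-child event times and structural containment of every
lineage.

## Loss accounting is derived, not accumulated

The engine records exactly one non-loss event per parasite internal node
(its *anchor*).  Losses are recomputed from the finished mapping: the
lineage leading to a child is charged one loss per host divergence it
crosses between its start point (the anchor's child-edge) and its own
anchor.  Nothing is charged above the parasite root — the host that
predates the parasite's arrival is ignored.  Three properties fall out of
this design rather than needing enforcement:

* the Jungle decomposition `total == 0·C + 1·D + 2·S + 1·L` is an identity
  against the re-tallied event list;
* relocating a switch's **take-off** edge along its path is cost-neutral
  (the crossings move between the parent lineage and the take-off lineage,
  a telescoping sum), while relocating the **landing** edge deeper strictly
  removes crossings — which is why Right Push is provably monotone;
* leftover parasite nodes appended above the host root (terminal state of
  the collapse) need no special loss rules.

## The collapse engine

Host internal nodes are processed deepest-first (a bucket keyed by depth —
depths are a permutation, so scheduling is linear).  By induction the two
children of the processed node are live leaves, i.e. a cherry.  Candidate
patterns are parasite cherries with a leaf resident on the host cherry:

| pattern | geometry at host cherry (A,B) | events | local cost |
|---|---|---|---|
| CODIVERGENCE | parasite cherry spans A and B | codivergence | $w_C$ |
| DUPLICATION | parasite cherry on one side | duplication | $w_D$ |
| HOST_SWITCH | one leaf inside, one outside | switch | $w_S$ |
| CODIV_SWITCH | codiv cherry + outside sibling, or switch cherry + sibling on the other side | codiv + switch | $w_C + w_S$ |
| DUP_SWITCH | dup cherry + outside sibling | dup + switch | $w_D + w_S$ |
| LOSS_SWITCH | switch geometry, committed through the collapsing parent | switch (+ derived loss) | $w_L + w_S$ |
| DOUBLE_SWITCH | switch cherry + second outside sibling | two switches | $2 w_S$ |
| DEFER_CODIV | switch partner sits on the host cherry's live sibling | loss now, certain codivergence one level up | $w_L + w_C$ |

Detection is a bounded walk — a resident leaf, its sibling, their parent
and the parent's other child; never more than four parasite levels, a
constant per candidate.  Selection takes the minimum local cost, ties
broken by a fixed kind priority (hybrids ahead of the base pattern they
extend), then by discovery order.  Design notes:

* **Hybrids under Jungle.**  With codivergence free, any hybrid containing
  a plain codivergence sub-match is cost-dominated by it.  The orientation
  that matters in practice is the *switch-below / codivergence-above*
  form, which ties the plain host switch at cost 2 and wins on priority,
  committing the coordinated pair of events at the deep position.  Under
  non-default weight schemes the other orientations become live; all are
  implemented and unit-tested.
* **DEFER_CODIV** is this package's one-level lookahead: when the switch
  partner already sits on the host cherry's sibling, losing the cherry now
  guarantees a codivergence at the parent for total $w_L + w_C = 1$,
  cheaper than the switch's $w_S = 2$.  Without it the greedy pays 2 where
  the optimum is 1 on the simplest loss instance.
* **Multiple codivergences per host node.**  Codivergence-bearing patterns
  do *not* collapse the host cherry immediately; the cherry collapses when
  no pattern is left.  Several parasite lineages (e.g. gene-family-like
  duplicated copies) may all codiverge at the same host divergence, as any
  exact method would place them.  With immediate collapse the greedy
  averaged 2–5× the optimum on multi-copy instances; with this rule it
  averages within a few percent of the exact DP on the default synthetic
  world.
* **Switch anchors.**  A committed switch takes off from the processed
  cherry's edge at time $d(v)$ and lands on the edge above the partner's
  live position.  Both edges are provably alive at $d(v)$ — collapsed
  positions are deeper, unprocessed ancestors shallower — which is the
  whole time-consistency guarantee; no global check is ever needed.

Complexity: pending parasite cherries are kept in per-host-node lists that
are spliced into the parent when a cherry collapses; collapsed host nodes
are tracked union-find style, so waiting lineages cost nothing until they
pair.  Matches are bucketed by kind (local cost is a function of the kind
only), so selection pops are amortised O(1).  The exposed elementary
operation counter is flat per node on congruent instances and fits a
linear model with $R^2 > 0.999$ on the default world from 8 to 1024 host
leaves.

## Right Push

Each switch is revisited bottom-up (children first).  With the take-off
child anchored at $s$ and the landing child at $t$, the deepest legal time
is $\tau^* = \min(\tau_s, \tau_t, d(s)-1, d(t)-1)$ — bounded by the
children's own event times and positions.  Level-ancestor queries (jump
pointers over the ordering depths; only the query contract matters)
retrieve the unique edges alive at $\tau^*$ on the two root paths; the
landing-side crossings between the old and new edges are reclaimed as
removed losses.  Pushing never moves an edge upward, never changes any
non-loss count, preserves the audit, and is idempotent (the fixed point is
$\tau^*$ itself).  Gains are largest when a landing child is a merged node
whose own anchor lies far below its live position; because the engine
already lands on the partner's live edge, small instances are often
already optimal and the average improvement on the default world is
modest.

## The genetic algorithm

Chromosomes carry one depth gene per non-root internal host node, bounded
below by the number of ancestors (the root included) and above by the
internal-node count minus the node's internal descendants minus one.
Defaults are 100 generations with a population of 100; selection is a
size-2 tournament, crossover uniform, mutation resamples each gene with
probability $1/\#\text{genes}$, repair resamples only conflicting genes
(bounded rounds, deterministic fallback), and one elite survives, so the
best-so-far cost is monotone.  Operators are this package's standard
choices — the reference framework does not prescribe them.  Tests run
scaled-down configurations (e.g. 10×5); reproducibility and monotonicity
do not depend on the scale.

## Oracle and baselines

`exact_dp()` computes the true optimum for a fixed ordering by dynamic
programming over (parasite node, host edge, time interval), with switch
transitions restricted to co-alive edge pairs and free entry of the
parasite root (no charges above its placement, matching the engine's
accounting).  It is deliberately guarded to ≤ 12 host leaves; a second,
memo-free enumerator cross-validates it on tiny instances so the two
oracles cannot share a bug.  `page_reconcile()` is the classical
switch-free LCA reconciliation (optimal among switch-free mappings,
ordering-independent), and equals the DP under a prohibitive switch
weight.  `edge_only_map()` — duplications and switches in the final
interval only — is realised as the DP with prohibitive codivergence/loss
weights and upper-bounds any all-events optimum.

A caution the test-suite encodes: the *greedy* has no per-instance
relation to the edge-only baseline.  A congruent parasite chain anchored
deep in the host can be resolved by the greedy as a cascade of switches
whose ancestors then pay repeated crossings, exceeding the loss-free
baseline on that instance (about 1% of default-world instances).  The
greedy-versus-edge-only comparison is therefore asserted as an aggregate
mean, which is also how the corresponding published totals are reported;
the DP-versus-edge-only bound holds per instance and is asserted per
instance.

## The synthetic generator

`yule_tree()` grows the host as a pure-birth process (uniform random
extant lineage splits).  `evolve_parasite()` co-simulates the parasite
down the host: at each host divergence a lineage faces, **one** event is
drawn — codivergence (track both children), loss (track one), duplication
or switch.  Daughters created by a duplication or switch resolve the
divergence they are facing with the renormalised codivergence/loss draw,
so each lineage triggers at most one independent event per host node.  (An
earlier variant let daughters re-draw the full menu at the same node; the
resulting geometric duplication cascades produced parasites an order of
magnitude larger than their hosts, which no Yule-style cophylogeny corpus
resembles and which degrades every method pathologically.)  Switch
landings are drawn uniformly among edges alive in the interval just before
the divergence — time-consistent by construction; at the root no such edge
exists and the draw is renormalised.  Losses track one child, so the
parasite cannot go extinct; single-leaf parasites are possible and are
redrawn by `generate_instance()`.

The default probabilities $(0.5, 0.2, 0.15, 0.15)$ for
codivergence/duplication/switch/loss are this package's declared stand-in
for the unpublished parameterisation of the reference generator: a
codivergence-dominated regime with all four events present, giving
parasites commensurate with their hosts (mean leaf ratio ≈ 1.2–1.5).  What
a green test on this world establishes: correctness properties
(feasibility, monotonicity, decompositions, determinism, scaling) and the
direction of the hybrid/Right-Push effects.  What it does not establish:
agreement with any published corpus totals, robustness to empirical tree
shapes (clock violations, unbalanced trees, widespread parasites), or the
behaviour of multi-host associations, which the data model excludes.

## Numerical and degenerate-input choices

* Times are integers; intervals half-open; ties between a parent and child
  event in the same interval are legal and ordered by topology.
* Leftover parasite nodes are appended above the host root as
  duplications with `pre_root = TRUE` and time index 0; the audit skips
  the span check for them.
* Single-node trees are rejected as hosts everywhere; a single-leaf
  parasite is representable (it maps to $\varphi$ with zero cost).
* `exact_dp()` refuses hosts above 12 leaves with a distinct guard error
  (CLI exit 3); "infinite" weights are large finite penalties ($10^7$)
  to keep arithmetic exact.
* All randomness flows through R's RNG; every simulator and the GA are
  reproducible from a single integer seed.

## Known limitations

The greedy is exact only in the congruence limit; its gap to the DP is a
few percent on the default world but unbounded in principle (deep
congruent chains, above).  Hybrid patterns are largely cost-dominated
under the Jungle weights; their measured aggregate effect here is small
and direction-consistent, not the large corpus-level reductions reported
for pattern sets defined on other data.  The level-ancestor index uses
jump pointers (logarithmic queries); the constant-time schemes would only
matter at scales far beyond the test sizes.
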