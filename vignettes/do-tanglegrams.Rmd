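---
title: "Displacement-optimized tanglegrams: model, heuristic, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Displacement-optimized tanglegrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotangle)
```

## The problem

A tanglegram places two rooted phylogenies side by side and connects
leaves carrying the same taxon label.  Most layout methods for trees
minimize the number of crossings among these intertaxon lines.  This
package instead minimizes *displacement*: how far matched taxa sit from
each other vertically (taxon displacement, TD), and how far the endpoints
of reticulation edges are pulled apart within each network (reticulate
displacement, RD).  Displacement objectives reward layouts that align the
shared structure of the two phylogenies row by row, and they extend
naturally from trees to rooted phylogenetic networks, where crossing-free
drawings generally do not exist.  Crossings are still counted and
reported, but they are never the optimization target.

## Data model

A rooted phylogenetic network on a taxon set $X$ is a directed graph
$N = (V, E, \rho, \lambda)$ with (1) an acyclic edge set, (2) a unique
in-degree-0 root $\rho$, (3) a bijection $\lambda$ between $X$ and the
out-degree-0 nodes, (4) no node with in-degree 1 and out-degree 1, and
(5) leaves of in-degree at most 1.  Multifurcating (out-degree $> 2$) and
multicombining (in-degree $> 2$) nodes are allowed; a tree is the special
case without reticulations.  `validate_network()` checks exactly these
five conditions and names the violated one.

Reticulations come in two flavors.  A *transfer* node models horizontal
transfer: one incoming edge (the transfer-acceptor edge) is the main
lineage, all others carry transferred material and are the reticulate
edges.  A *combining* node models hybridization: all incoming edges are
equal and all are reticulate.  In eNewick input, an `[&acceptor]` comment
on an occurrence of a `#H` label marks the corresponding incoming edge as
the acceptor; without any mark a reticulation is treated as combining.
No standard file convention exists for acceptor edges, so the comment tag
is this package's own convention (and the only place where one was
needed).

### Backbone reduction and coordinates

`backbone_tree()` converts every reticulation into a tree node: transfer
nodes drop their non-acceptor edges; combining nodes are re-hung below
their lowest stable ancestor (LSA), the node nearest to them that lies on
every path from the root.  LSAs are computed once per network as graph
dominators (a single sweep in topological order suffices on a DAG) and
cached in the backbone object; child reordering never invalidates them.
The result spans all original nodes and may legitimately contain
unlabeled leaves and through nodes; these are kept, occupy leaf rows in
the drawing, but never enter rankings or TD.

Given a child order for every backbone node, leaves receive
$y = 1, \dots, L$ in traversal order, an internal node the mean $y$ of
its leaf descendants (labeled or not), and $x$ = edge count from the
root.  Branch lengths are parsed and preserved in output but ignored by
all layout computations, which are purely ordinal.

## Scores

With shared taxa $X = X_1 \cap X_2$, $|X| = n$, and rankings
$\pi_i : X \to \{1,\dots,n\}$ from the traversal order of each side:

$$\mathrm{TD}(O_1, O_2) = \sum_{t \in X} |\pi_1(t) - \pi_2(t)|, \qquad
\mathrm{RD}(N, B, O) = \sum_{(v,w) \in R} |y(v) - y(w)|.$$

TD is always computed on ranks over the shared taxa, even when the taxon
sets coincide: the rank form is the one that remains well defined with
missing taxa, and it coincides with the raw-row form for equal complete
leaf sets.  The one-sided score is
$\mathrm{OSTS} = \alpha\,\mathrm{RD}(N_2) + \beta\,\mathrm{TD}$ and the
two-sided score
$\mathrm{TSTS} = \alpha\,\mathrm{RD}(N_1) + \beta\,\mathrm{TD} +
\gamma\,\mathrm{RD}(N_2)$, with $\alpha, \beta, \gamma \in \{0, 1\}$
(`score_config()`).  Crossings are counted over shared taxa only, by
merge-sort inversion counting.

## The heuristic

Both the one-sided problem on networks and the two-sided problem on
binary trees are NP-hard, so optimization is local:

1. **Per-node search** (`optimize_children()`).  In a preorder traversal
   of the free backbone, each node's child order is optimized while
   everything else stays fixed.  Up to 8 children, all permutations are
   enumerated and the exact local argmin taken (ties: first permutation
   in lexicographic generation order, so the current order wins a tie).
   Beyond 8, simulated annealing over uniform pair swaps with Metropolis
   acceptance $\exp(-\Delta/T)$ is used; the best state ever visited is
   returned, so a local step can never lose ground.
2. **Local objectives.**  At nodes that are the LSA of some reticulation
   or the source of a transfer edge the local objective is the OSTS; at
   all other internal nodes it is the TD alone.  Permuting one node's
   children only shifts contiguous leaf blocks, so both terms split into
   a constant and a cheap block-offset part; the local evaluator is exact
   (tested against from-scratch recomputation for every permutation).
3. **Smallest-rank candidate.**  Before searching, children are ordered
   by the smallest reference rank among the shared taxa below them
   (children without shared taxa keep their slots) and this candidate is
   evaluated first.  It repairs the star-tree weakness of a pure swap
   search and is used at every node where a reference ranking exists, RD
   nodes included.
4. **Verification sweeps.**  One preorder pass is followed by further
   passes until a pass brings no score improvement (at most 20).  This is
   a design choice: a single pass leaves occasional second-order gains on
   the table, and the sweep keeps the one-sided result a local optimum of
   the pass operator at negligible cost.
5. **Two-sided alternation** (`two_sided_optimize()`).  Side 2 is
   optimized against side 1, then roles switch; a round that fails to
   lower the TSTS stops the loop (default cap: 10 rounds — the stopping
   rule is not prescribed anywhere, and in practice 2–4 rounds suffice).
   The TSTS is non-increasing by construction, which the tests assert.
6. **Restarts** (`optimize_with_restarts()`).  `jobs` independent runs:
   job 0 starts from the NN-presorted (or as-input) orderings, later jobs
   from random child orders — below every internal node for trees, below
   the LSA nodes for networks.  Job $i$ is seeded with `seed + i` and the
   winner chosen by (score, crossings, job index), so the result is
   bit-reproducible regardless of execution order; parallelism is a
   contract, not a primitive, and the implementation runs jobs
   sequentially.

### Neighbor-net presorting

The presorting step extracts all hardwired clusters of both networks (the
shared-taxon sets below tree nodes, size $\ge 2$), builds the distance
$D(i,j)$ = number of clusters containing exactly one of $i, j$, and runs
the agglomerative phase of neighbor-net on $D$ to get a circular taxon
order.  For tree inputs, $D$ is exactly the path metric of the tree with
unit weight per cluster, so the circular order makes every cluster a
contiguous arc (a property test checks this), and presorting both sides
by average rank yields a crossing-free start whenever the cluster sets
are compatible.

Two conventions had to be fixed here.  First, the neighbor-net internals:
the implementation follows the published agglomerative phase — cluster
pair by the neighbor-joining criterion
$Q(A,B) = (m-2)\,d(A,B) - \sum_C d(A,C) - \sum_C d(B,C)$ with mean
linkage, node pair among cluster endpoints by the analogous node-level
criterion, and 3-node paths $x\!-\!y\!-\!z$ reduced to two nodes with
$d(u,w) = \tfrac23 d(x,w) + \tfrac13 d(y,w)$,
$d(v,w) = \tfrac13 d(y,w) + \tfrac23 d(z,w)$,
$d(u,v) = \tfrac13(d(x,y)+d(y,z)+d(x,z))$, expanding the reductions in
reverse at the end; all ties break toward the lowest taxon index.
Second, the circular order must be cut to yield ranks: it is cut
immediately before the lexicographically smallest shared taxon, walking
toward its lexicographically smaller neighbor.  Any common cut works —
both sides use the same one — but different cuts can produce different
(equally legitimate) presorts on asymmetric inputs.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha`, `beta`, `gamma` | 1, 1, 1 | 0/1 weights of RD1, TD, RD2 |
| `start_temperature` | 1000 | initial Metropolis temperature (score units) |
| `end_temperature` | 0.01 | annealing stops below this temperature |
| `iterations_per_step` | 1000 | proposals per temperature step |
| `cooling_rate` | 0.95 | geometric cooling factor per step |
| `exhaustive_threshold` | 8 | children up to which search is exhaustive |
| `jobs` | 32 | independent seeded restarts |
| `max_rounds` | 10 | cap on two-sided alternation rounds |

The annealing defaults are the method's published advanced settings
(about 225 temperature steps, i.e. 225 000 proposals per annealed node).
The test suite substitutes a scaled-down schedule (100 → 0.1, 200
proposals, cooling 0.9) purely for runtime; binary-tree instances never
reach the annealing regime, so this affects only heavily multifurcating
nodes.

## Synthetic benchmarks

`generate_pair()` reproduces the benchmark construction used to evaluate
the method: a random 500-taxon binary background tree (grown by uniform
random leaf attachment — the background tree's shape is otherwise
unspecified, and leaf attachment is the simplest exchangeable choice); an
induced subtree on $n$ random taxa ("subtree on $n$ taxa" is read as the
induced restriction, since clades of an exact size need not exist); in
tree mode two copies perturbed by $\mathrm{round}(r \cdot n)$ rooted SPR
moves each; deletion of a proportion $m$ of taxa and contraction of a
proportion $c$ of internal edges per copy (all rounding half-up); and in
network mode $k$ reticulations added per copy by the standard
double-subdivision construction, with the acyclicity condition that the
head edge's child is not an ancestor of the tail edge's parent.  The
published grids are $n \in \{50,\dots,450\}$, $r \in \{0.1,0.2,0.3\}$,
$m \in \{0,0.1\}$, $c \in \{0,0.1\}$ for trees and
$n \in \{50,\dots,400\}$, $m \in \{0,0.05\}$, $c \in \{0,0.05\}$,
$k = 10$ for networks; the acceptance tests sample these grids at reduced
size to stay within their runtime budget.

What the generator does *not* emulate: biologically calibrated branch
lengths (there are none — all layouts are ordinal anyway), non-uniform
discordance such as localized transfers, correlated missingness between
the sides, or empirical label conventions.  A green synthetic test
therefore establishes algorithmic correctness and the claimed structural
properties (zero crossings for compatible inputs, monotone improvement,
determinism), not performance on any particular empirical dataset.  The
comparison against the published fig-wasp and grass layouts requires the
original data files, which must be fetched from the method's public data
repository; in an offline build that acceptance test fails and is
documented as such rather than being skipped.

## Numerical conventions and degenerate inputs

Leaf rows and ranks are integers; internal $y$ values are means of
integers, held as doubles, with $10^{-9}$ tolerance wherever scores are
compared for equality (monotonicity checks).  Tie-breaking is everywhere
deterministic: lexicographic-first in exhaustive search, lowest taxon
index in neighbor-net, stable sorts in all rank-based reorderings, and
(score, crossings, job index) across restart jobs.  All randomness flows
from explicit seeds; the caller's RNG state is saved and restored.
Degenerate cases: phylogenies sharing no taxon are rejected up front; a
single shared taxon yields TD = 0 trivially; nodes with one child are
never searched; children whose subtrees hold no shared taxon are never
reordered relative to each other by rank-based steps.  Unrooted or
multi-rooted inputs are rejected rather than silently rooted.

## Known limitations

- All optimization is heuristic; no optimality guarantee exists beyond
  the exhaustive regime, and the micro-scale acceptance test quantifies
  the gap (the enumerated optimum is reached in $\ge 90\%$ of 7-leaf
  instances, and never undercut).
- eNewick cannot express where an LSA-replacement child sits among its
  backbone siblings, so re-parsing a written *network* reproduces the
  topology (isomorphism is tested) but may place re-hung reticulation
  subtrees after their siblings; for trees the round trip is exact,
  ordering included.
- The implementation is pure R; very large, heavily multifurcating
  networks will be slow under the full annealing schedule.  Reducing
  `iterations_per_step` or `jobs` trades quality for time.
- Taxon matching is exact label equality; many-to-many matching is out of
  scope.
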