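---
title: "weavenet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{weavenet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weavenet)
```

## The model

weavenet represents an organism's molecular interactions as a single mixed
graph: proteins are nodes, undirected edges record physical (PPI) binding,
and directed edges record transcription-factor regulation. A protein pair
may carry a physical edge *and* regulatory edge(s) at once; these are kept
as distinct parallel edges, because collapsing them would make several of
the 3-node motif classes indistinguishable (a mixed feedback loop would
read as a feed-forward loop). Gene Ontology terms attach to this graph
through annotation edges, either direct (curated) or inferred by the
true-path rule: a protein annotated to a term is implicitly annotated to
every ancestor of that term.

### Annotation propagation

Propagation traverses `is_a` and `part_of` parents only (configurable).
Regulates-type relations are not traversed: their semantics do not license
membership inheritance. The namespace roots are excluded from inferred
annotations — every protein would otherwise be annotated to them, and a
term to which everything belongs carries no ranking information.
Propagation is idempotent, and direct records are never downgraded when an
ancestor is also directly annotated.

## Subnetwork queries

Both query modes connect a query protein $s$ to the proteins annotated to
a GO term $t$ over a chosen edge-type filter (physical, regulatory, or
mixed), with a size parameter $k$ (typically 5–25):

* **K unique paths** returns the $k$ globally shortest simple paths, by
  edge count, from $s$ to *any* annotated protein. Several paths may end
  at the same protein, and paths may pass through annotated proteins on
  the way to a farther terminal.
* **K unique nodes** returns the $k$ annotated proteins nearest to $s$ by
  breadth-first-search distance, each connected through one witness
  shortest path so the result stays a connected subnetwork.

Three choices here were genuinely open and are fixed as follows:

* *Regulatory edges are traversed in both directions* during path search;
  their true direction is preserved in results and in motif counting. A
  path from a target gene up to its regulator is biologically meaningful
  context, and single-direction traversal would make many queries empty.
* *Deterministic tie-breaking.* Among equal-length paths (or
  equal-distance nodes) ties are broken lexicographically on the node-id
  sequence, compared bytewise so results do not depend on the session
  locale. This makes query output reproducible and prefix-stable: the
  first $k$ paths of a $k' > k$ query equal the $k$-query output. The
  search is a best-first expansion of partial simple paths keyed by
  (length + exact BFS lower bound to the target set, node sequence), which
  emits paths in exactly that order.
* *A source annotated to its own query term* is excluded from the target
  set, so the query finds its connections to the *other* members of the
  term rather than a trivial zero-length path.

Parallel physical + regulatory edges between consecutive path nodes count
as one step; paths are node sequences and both parallel edges are included
in the rendered subnetwork.

## The five motif classes

On any three distinct proteins the induced mixed subgraph is classified
into: protein clique (all three physical pairs), feed-forward loop (TF X
regulates TF Y, both regulate Z), mixed feedback loop (a feed-forward loop
whose TFs also physically interact), interacting coregulators (physical
pair jointly regulating a target), and coregulated interactors (one TF
regulating a physical pair). All node orderings and both orientations of
reciprocal regulation are tried when matching.

Overlap resolution: the mixed feedback loop always wins over the
feed-forward loop (the defining disambiguation of the mixed graph). The
protein clique is tallied independently of the regulatory/mixed family —
a clique whose members also regulate each other counts in both tallies,
which matches the observation that PPI-rich networks show large clique
proportions irrespective of their regulatory structure. Within the
regulatory/mixed family, when several patterns co-occur the order is
mixed feedback loop > feed-forward loop > interacting coregulators >
coregulated interactors: patterns with more matched edges win, so adding
regulatory detail can only move a triple toward a more specific class.

The census enumerates closed triangles of the union adjacency (every class
requires all three pairs adjacent), which provably equals full
$O(n^3)$ triple enumeration; the test suite asserts that equality on
hundreds of random graphs.

### Enrichment

Motif enrichment of a queried subnetwork is judged against a Monte-Carlo
null: census counts on random *connected induced* subgraphs of the same
node count, grown by snowball sampling from a uniformly chosen seed node.
Connectivity matching matters because queried subnetworks are connected by
construction, and connected regions of a sparse graph are motif-richer
than arbitrary node sets. Reported per class: observed count, null
mean/sd, the enrichment ratio (NA when the null mean is 0), a Z-score
(0 when sd is 0 and the observation equals the mean), and the empirical
upper-tail p-value with the add-one correction
$p = (1 + \#\{null \ge obs\}) / (reps + 1)$, which never reports an exact
zero at finite replicates. Replicates and seed are recorded in the report;
999 replicates is the default.

## Scoring protein–GO association

Four scores rank how strongly a protein $s$ associates with a term $t$:

* **RandomWalk** — personalized PageRank with damping $\alpha = 0.7$:
  $p = (1-\alpha)\,r + \alpha\,W^{\top}p$, restart uniform over the
  proteins annotated to $t$ (direct or inferred). The walk substrate
  defaults to the full composite graph: interaction edges plus
  protein–term annotation edges, all treated as undirected with uniform
  transition probabilities; dangling nodes redistribute to the restart
  vector. `annotations_only` and `interactions_only` substrates are
  switches for ablation. Power iteration stops when the L1 change falls
  below 1e-10 (default; max 1000 iterations), and the result sums to 1
  within 1e-9. Under this convention the restart probability is
  $1-\alpha = 0.3$, and the restart set always retains at least
  $1-\alpha$ of the total mass.
* **Degree** — the protein's degree in the whole mixed graph; ignores $t$
  and serves as the degree-bias control.
* **One-hop overlap** — the number of the protein's neighbors annotated
  to $t$.
* **Hypergeometric** — the upper-tail probability of observing that
  overlap given the term size and the protein's degree (population = all
  proteins, draws = degree, capped at the population size); smaller is
  better.

Ranks are competition ranks in each method's better-direction, with
lexicographic protein-id ordering used only to make reported orderings
deterministic.

## The evaluation harness

The benchmark removes one direct annotation edge (a sampled positive),
also dropping inferred ancestor records left without direct support, and
asks each method to re-find it against up to 100 matched negatives per
positive. Negatives must simultaneously (1) lie near the positive protein
on the interactions-only view — within 2 hops, relaxed to 3 then 4 when
fewer candidates exist, with the relaxation recorded; (2) not be annotated
to the positive's term, directly or by inference — never relaxed; and
(3) match the positive's degree within $\max(2,\ 10\%)$. Each trial is
isolated: the input annotation set is never mutated.

Scores from different trials (different terms, different scales) are
pooled on a common scale: the within-trial normalized rank
$\mathrm{rank}/(1+\mathrm{candidates})$, negated so larger means stronger.
ROC curves use a threshold sweep with trapezoid area (the area equals the
normalized Mann–Whitney statistic; the suite asserts this identity) and
precision–recall uses step interpolation.

## The synthetic fixture generator

Fixtures emulate the study conditions end to end: an Erdős–Rényi PPI
background over 500 proteins (mean degree 36 — curated mixed networks are
dense; real interactomes carry hubs with thousands of partners), 20 leaf
GO terms under a two-level ontology, and per term a planted cluster of 45
members whose within-cluster PPI probability is exactly
`density_boost` (default 3) times the background probability. Each
cluster also receives 5 dedicated regulators — TFs that drive every
member but are *not* members themselves, reflecting that regulators of a
process are frequently not annotated to it. This regulator-mediated
2-hop association is precisely the signal a walk over the mixed graph can
exploit and neighbor-overlap scores cannot. Only a `completeness`
fraction (default 0.8) of true members is annotated; the rest are hidden
members, the natural recovery targets.

What the fixtures do *not* emulate: heavy-tailed degree distributions,
evidence-code structure, namespace mixtures, and the deep, diamond-rich
real GO hierarchy. Passing tests therefore demonstrate algorithmic
correctness and the *direction* of method differences, not the absolute
performance figures attainable on curated species networks.

Two measured properties of the generator, computed by the test suite at
fixed seeds, are worth recording:

* Under the reference conditions (3× boost, completeness 0.8, 50
  positives × 50 negatives, 5 seeds) the RandomWalk's ROC AUC averages
  about 0.91 and strictly exceeds the degree, one-hop and hypergeometric
  AUCs in every seed.
* Hidden members rank in the top decile of the walk's candidate ranking
  on average only when the planted structure is stronger (about 5–6×
  boost at these densities); at 3× they land around the top 15–20%. Two
  effects cap recovery at 3×: hidden members carry no annotation edges at
  all, and — by the negative-sampling rules — hidden members of a term
  are themselves eligible negatives for that term's positives, so some
  "false positives" are in fact unlabeled true members.

## Numerical and degenerate-input choices

* Node-id comparisons and orderings are bytewise (radix), never
  locale-dependent.
* Physical self-loops are dropped at graph construction (with a count);
  regulatory self-loops are kept as data but ignored by path queries and
  the motif census, which require distinct nodes.
* Queries whose target set is empty or unreachable return an empty,
  well-formed subnetwork with a diagnostic message, not an error; unknown
  proteins or terms are errors.
* The hypergeometric draw count is the mixed degree capped at the
  population size (parallel edges can push the raw degree past it).
* PageRank non-convergence within the iteration cap is an error carrying
  the residual, never a silent partial result.
* Fixture generation restores the caller's RNG state; identical
  specifications yield byte-identical serialized bundles.

## Problem sizes used by the test suite

Oracle comparisons run on hundreds of random graphs of 8–15 nodes (where
exhaustive enumeration is exact), the walk is verified against dense
linear solves at 20 nodes, and the method-dominance experiment runs the
full 500-protein reference conditions over 5 seeds with 50 positives × 50
negatives. These sizes make every check an exact or statistically
calibrated comparison while keeping the default suite fast.

## Known limitations

* The enrichment null model (uniform connected induced subgraphs) is one
  defensible choice; a degree-preserving edge-swap null is a possible
  extension and would judge hub-heavy subnetworks differently.
* The k-shortest-paths search is exact but exponential in the worst case;
  it is intended for the interactive regime (small k, local
  neighborhoods), not for graph-scale path enumeration.
* Ranking candidates are "proteins not annotated to t"; when annotation
  is incomplete that candidate set contains unlabeled true members, which
  bounds every method's measurable precision.
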