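---
title: "Pareto-optimal DTL reconciliation across event cost space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto-optimal DTL reconciliation across event cost space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reconscape)
```

## The model

A reconciliation instance is a *tanglegram*: a rooted binary gene
(parasite) tree $T$, a rooted binary species (host) tree $S$, and a total
association of the tips of $T$ with tips of $S$ (many-to-one allowed).  A
*DTL scenario* maps every node of $T$ to a node of $S$ and labels every
internal node of $T$ as a speciation, duplication or transfer, subject to
the usual validity constraints: tips map to their associated tips; a
node's image is never a proper descendant of a child's image, and at
least one child image descends from it; an edge is a transfer edge
exactly when its endpoints' images are incomparable; a speciation sits at
the LCA of its children's (incomparable) images; a duplication sits at or
above that LCA; and a transfer's recipient is incomparable to the source
and ancestral to the transferred child's image.  Losses are not labelled
nodes but are counted from the mapping: a lineage that enters a species
branch and bypasses one side of a speciation pays one loss per bypassed
branch (a speciation's own divergence is free; a duplication's and a
transfer's are not).

Each scenario has an event count vector $\langle\delta,\theta,\ell\rangle$
(duplications, transfers, losses; the number of speciations is implicit,
$m-1-\delta-\theta$ for $m$ gene tips).  With speciation free and positive
costs $C_\Delta, C_\Theta, C_L$, the reconciliation cost is
$C_\Delta\delta + C_\Theta\theta + C_L\ell$.  Rather than fixing costs, the
package computes every *Pareto-optimal* vector: those not strictly
dominated componentwise by any other achievable vector.  Every fixed-cost
optimum is attained on this front, for any positive costs.

### The dynamic program

`pareto_reconcile()` runs a nested post-order traversal of $T$ and $S$
maintaining, per pair $(t, s)$, the Pareto set of vectors for reconciling
$T(t)$ with $S$ such that $t$ maps to $s$, split by the event at $t$.
Two closed operations drive it: the merge $\oplus$ (union, then Pareto
filter) and the combine $\otimes$ (Cartesian sums, then Pareto filter).
The combine is implemented with a sorted-list procedure keeping at most
one entry — the minimum-loss one — per $(\delta,\theta)$ pair, so
intermediate lists never exceed one entry per pair; a final filter
removes cross-pair domination.  Auxiliary tables reuse work: `in(t,s)`
(map $t$ anywhere below $s$, one loss per edge descended), `inAlt(t,s)`
(the same without loss charges) and `out(t,s)` (map $t$ anywhere
incomparable to $s$ — the transfer landing sites).

Annotations ride along the same algebra.  Reconciliation *counts* add
across alternative derivations of a vector ($\oplus$) and multiply across
composed subsolutions ($\otimes$).  *Common events* — events present in
every reconciliation achieving the vector — intersect across alternatives
and union across compositions.  Transfer events are the delicate case:
their identity includes the recipient species, which is the top mapping
of the out-side subsolution, so `out` entries carry the set of possible
top mappings and a transfer event is attached only when that set is a
singleton.  Both annotations are verified against exhaustive scenario
enumeration on random tiny instances (fronts, counts and common-event
sets all match exactly).

## Design choices

Several points are underdetermined by the problem statement; the package
resolves them as follows.

**Canonical transfer recipients.**  The validity constraints allow a
transfer recipient anywhere incomparable to the source and ancestral to
the transferred child's image, but any recipient strictly above that
image only adds losses and is dominated.  Scenario identity, counting and
enumeration therefore fix the recipient to the transferred child's image
(zero-distance landing), which is also what the dynamic program computes.

**Speciation/duplication dual labelling.**  A node whose children's
images are incomparable and whose own image is exactly their LCA
satisfies the eligibility conditions of both speciation and duplication
(both are "only if" constraints).  The two labelings are distinct
scenarios and both are enumerated and counted; domination removes the
duplication variant from the front (it has one more duplication and two
more losses), so front annotations are unaffected.

**Infeasibility.**  Infeasible cells are empty Pareto sets — the
$\oplus$ identity and the $\otimes$ absorber — rather than an
$\langle\infty,\infty,\infty\rangle$ sentinel; this avoids infinity
arithmetic and needs no special cases.

**`out` at gene leaves, transfers at the species root.**  The transfer
recurrence at an internal gene node consumes `out` at its children,
which may be leaves, so `out` is computed for every gene node.
`out(t, rt(S))` is identically empty: no species node is incomparable to
the root, so transfers cannot land from the root cell and the transfer
case is skipped there.

**Equality in the combine.**  When two pairs produce the *same* vector,
the sorted-list deletion rule would discard one; with annotations the
duplicate must instead be merged (counts add, per-pair event unions
intersect).  The implementation merges on exact vector equality.

**Event identity.**  Events use the most specific identity: event type
plus gene node plus species node; transfers additionally carry the
transfer edge and the recipient; losses are located by a gene branch (the
edge above the surviving gene node) and a species branch (the bypassed
side).  Coarser identities can be derived from the serialized keys but
are not the default.

## Exact geometry of the cost-space partition

With duplication cost normalised to 1, the cost of vector $v$ at the point
$(x, y) = (C_\Theta, C_L)$ is affine, so the region where $v$ is optimal
within a cost box is the intersection of the box with the half-planes
$(\delta-\delta') + (\theta-\theta')x + (\ell-\ell')y \le 0$ over the
competing vectors $v'$.  `cost_regions()` clips the box polygon against
each half-plane with Sutherland–Hodgman in exact rational arithmetic:
coefficients are integer count differences and box bounds are rationals,
so every vertex stays rational.  This matters because regions routinely
degenerate to segments or points; whether a region has exactly zero area
is undecidable in floating point but trivial in rationals.  Regions are
closed, so boundary points belong to all touching regions; the region
count includes zero-area regions; dimension-2 areas sum exactly to the
box area (asserted as rational equality in the tests).  A small
hand-written rational module backs this (no rational-arithmetic package is
available in the dependency set); numerators and denominators stay far
below $2^{53}$, where double-held integers are exact.

Consensus support follows directly: an event's region-fraction support is
the proportion of regions in which it is common to every reconciliation
(zero-area regions count as full regions — the measure counts regions,
not area), and its area-fraction support is the proportion of box area
covered by such regions (zero-area regions contribute nothing).  The set
of events with support at least $s$ is non-increasing in $s$ under both
measures.

## Permutation significance

`significance_grid()` tests, at each cell of a grid over the box, whether
the observed tanglegram reconciles more cheaply than tip-shuffled null
instances.  One Pareto front per permutation serves all cells, since the
minimum fixed-cost reconciliation cost is the front minimum of an affine
function; per-cell p-values computed this way are verified against
per-cell brute-force optimisation on tiny instances.  The p-value is the
add-one estimator $(1+r)/(N+1)$ with $r$ the number of permutations at
most as cheap as the observation — a standard choice that never returns
0; the exact estimator used by the original significance tools is not
specified in the available text, so the convention (and the null: target
multiset shuffle by default, uniform reassignment optionally) is
configurable.  Cell costs are evaluated with the common denominator of
all cell coordinates cleared, so comparisons are exact integer
comparisons.  Defaults follow common practice for this analysis: a
100×100 grid, 1000 permutations, shuffle null.  Cost-class fractions are
reported with strict lower boundaries ($p < 0.01$,
$0.01 \le p < 0.05$, $p \ge 0.05$).

## The synthetic generator

`simulate_cophylogeny()` produces test instances, not biology.  A uniform
random binary species topology is grown by random joins; a gene lineage
then descends from the root, co-diverging at speciations, and on each
species branch may duplicate in place, transfer one copy to a uniformly
chosen incomparable branch, or die, each with a fixed per-branch
probability (defaults 0.1/0.1/0.1 on 6 species tips — small enough that
instances stay tractable for exhaustive enumeration yet produce diverse
mixed event histories; the documented operating envelope, probabilities
up to 0.3 on up to 8 tips, is exercised in the tests).  Dead lineages are
pruned; draws with fewer than two surviving gene tips are rejected and
resampled.  The realised history is returned as a valid DTL scenario of
the pruned instance, which gives every property test a known upper bound:
the front can never be beaten by the true history at any positive costs.
Two realism limits are deliberate: no dates or rate heterogeneity (the
model is topological), and rare multi-hop transfer chains whose pruned
trace is not expressible as a DTL scenario of the surviving tree are
rejected rather than repaired.  A green property suite therefore
establishes algorithmic correctness on valid instances — it says nothing
about inference accuracy on real data, which is out of scope.

## Numerical and degenerate-input policy

All cost comparisons, region boundaries and grid evaluations are exact
(rational or integer-scaled); floating point appears only in reports and
plots.  Single-tip gene trees reconcile trivially
($\langle0,0,0\rangle$); polytomies, duplicate tip labels and non-root
unary nodes are parse errors, while a redundant outer parenthesis pair is
collapsed.  Ties at region boundaries are genuine ties: `locate_point()`
returns every optimal vector, and closed regions overlap on their
boundaries by design.  Iteration orders (post-order by child index,
species pre-order) are fixed, so equal inputs give byte-equal outputs.

## Known limitations

Time-consistency of reconciliations is not enforced (finding optimal
time-consistent solutions is NP-hard; optima reported here may be
time-inconsistent).  Reconciliations are counted and summarised, never
enumerated — their number grows exponentially.  The cost space is the
two-dimensional normalised one (duplication fixed at 1); three-cost
partitions are out of scope, as are dated-tree variants and
whole-reconciliation consensus.
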