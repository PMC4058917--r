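# reconscape

Pareto-optimal duplication–transfer–loss (DTL) reconciliation and event
cost-space analysis for R.

## The problem

Phylogenetic tree reconciliation maps a gene (or parasite) tree *T* into a
species (or host) tree *S*, explaining the incongruence between them by
**d**uplications, **t**ransfers (host switches) and **l**osses, with
speciation as the free null event.  Maximum-parsimony reconciliation
assigns each event type a cost — C<sub>Δ</sub> for duplication,
C<sub>Θ</sub> for transfer, C<sub>L</sub> for loss — and seeks a valid
scenario minimising

C<sub>Δ</sub>·δ + C<sub>Θ</sub>·θ + C<sub>L</sub>·ℓ,

where ⟨δ, θ, ℓ⟩ is the scenario's *event count vector*.  The answer can
change qualitatively with the costs, and good costs are rarely known.

`reconscape` removes the need to commit to one cost choice.  It computes
the complete set of **Pareto-optimal** event count vectors — those for
which no valid reconciliation is componentwise at least as good and
strictly better somewhere — by a nested post-order dynamic program over
Pareto-set algebra (a merge ⊕ that unions and filters, and a combine ⊗
over Cartesian sums).  With duplication cost normalised to 1, each front
vector is optimal on a convex subset of the (C<sub>Θ</sub>, C<sub>L</sub>)
plane, so a user-chosen cost box is tiled exactly into **equivalence
regions** (polygons, segments or single points, computed in exact rational
arithmetic).  On top of this the package provides:

* per-vector **reconciliation counts** and the set of events common to
  *every* maximum-parsimony reconciliation in each region,
* **consensus support** for individual events, as the fraction of regions
  (or of cost-space area) in which the event is universal, and
* **permutation significance maps**: for each cost point, an add-one
  permutation p-value of the observed minimum reconciliation cost against
  tip-shuffled null instances.

Intended users: evolutionary genomicists reconciling gene families with a
species phylogeny, and cophylogeneticists analysing host–parasite
tanglegrams.

## Worked example

The minimal instance with a genuine cost trade-off: species tree
`((A,B),C)`, gene tree `(a,(b,c))`, tips associated a–A, b–B, c–C.

```r
library(reconscape)
inp <- recon_input(gene_tree = "(a,(b,c));", species_tree = "((A,B),C);",
                   mapping = c(a = "A", b = "B", c = "C"))
fit <- pareto_reconcile(inp)
summary(fit)
#> DTL Pareto front for 3 gene tips on 3 species tips
#>  duplications transfers losses speciations count common_events
#>             0         1      0           1     1             2
#>             1         0      3           1     1             5
```

Two Pareto-optimal histories exist: one speciation plus one transfer
(⟨0,1,0⟩), or one speciation, one duplication and three losses (⟨1,0,3⟩);
each is achieved by exactly one reconciliation.  At unit costs the
transfer history wins with total cost 1; if transfers cost 5 the
duplication history wins with total cost 4:

```r
min_cost_fixed(inp, event_costs(transfer = 1, loss = 1))$cost   # 1
min_cost_fixed(inp, event_costs(transfer = 5, loss = 1))$cost   # 4
```

Partitioning the cost box [0.1, 5]² splits it along the exact line
C<sub>Θ</sub> = 1 + 3·C<sub>L</sub>:

```r
reg <- cost_regions(fit, cost_box(0.1, 5, 0.1, 5))
summary(reg)
#> Cost box: transfer [1/10, 5], loss [1/10, 5] (duplication = 1)
#>  duplications transfers losses speciations count dimension      area area_exact
#>             0         1      0           1     1         2 21.728333  13037/600
#>             1         0      3           1     1         2  2.281667   1369/600

locate_point(fit, c(2, 1))      # the Jane/TreeMap default costs
#>      duplications transfers losses
#> [1,]            0         1      0
```

The transfer region covers 13037/600 of the 24.01 box area (≈ 90.5%), so
under the area measure the transfer event and its accompanying root
speciation have consensus support 0.905:

```r
consensus_support(reg, "area_fraction")
#> Event consensus support over 2 regions (measure: area_fraction)
#>         type n_regions region_fraction area_fraction
#>   speciation         1             0.5         0.905
#>     transfer         1             0.5         0.905
#>  duplication         1             0.5         0.095
#>  ...
```

A permutation test (tip associations shuffled, 99 permutations) shows a
3-tip tanglegram can never reach significance — the smallest attainable
p-value is (1+r)/(N+1) with only six distinct permutations:

```r
g <- significance_grid(inp, cost_box(0.1, 5, 0.1, 5),
                       grid = 10, n_perm = 99, seed = 1)
print(g)
#> Permutation significance map: 10x10 cells, 99 permutations (mode 'shuffle', seed 1)
#>   p<0.01: 0.0%   0.01<=p<0.05: 0.0%   p>=0.05: 100.0%
```

## Command line

A thin front end over the same functions is installed at
`inst/scripts/reconscape`:

```sh
Rscript inst/scripts/reconscape costscape --host s.nwk --parasite g.nwk \
    --mapping m.tsv --tmin 0.1 --tmax 5 --lmin 0.1 --lmax 5 --out r.json
```

Subcommands: `costscape` (region report), `eventscape` (consensus support
table), `sigscape` (significance grid; `--permutations`, `--grid`,
`--seed`, `--mode`), `simulate` (synthetic tanglegram fixtures).  Inputs
are Newick trees plus a tab- or colon-separated tip-association table, or
one combined file with `HOSTTREE` / `PARASITETREE` / `MAPPING` sections.

## Acceptance script

`scripts/acceptance.R` rebuilds the three-leaf worked instance from its
Newick strings, runs fixed-cost maximum-parsimony reconciliation through
the package at the two published cost settings (duplication = loss = 1
with transfer 1, then transfer 5), and writes the recomputed minimum
costs as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
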