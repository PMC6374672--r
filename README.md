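# phyloiso

**phyloiso** asks a simple, sobering question about a phylogeny: if the
species currently threatened with extinction disappear, how *phylogenetically
isolated* does a focal species become? It was built for conservation
phylogenetics — analyses of a timetree (e.g. the mammal supertree), a table
of IUCN Red List categories, and a focal species whose position on the
shrinking tree of life is the object of study.

## The method

The package scores each tip of a rooted, branch-length-bearing tree with the
**evolutionary distinctiveness** index (ED, also called the *fair
proportion*): every edge's length $L_b$ is split equally among its $n_b$
descendant tips,

$$ED_i \;=\; \sum_{b \in \mathrm{path}(\mathrm{root} \to i)} \frac{L_b}{n_b},$$

so that $\sum_i ED_i$ equals the tree's total branch length (total
phylogenetic diversity). Species are ranked from most (rank 1) to least
original, ties averaged.

On top of that score the package implements:

- **Sequential extinction scenarios** — all species in a nested doomed set
  ({CR}, {EN,CR}, {VU,EN,CR}, {NT,VU,EN,CR}) are pruned, ED is recomputed on
  the survivor tree, and the focal species' rank among survivors (*Obs.*) is
  reported. Data-deficient (DD) species are handled by extreme policies
  (all-LC / all-CR) or by imputation.
- **Monte Carlo null tests** — risk statuses are permuted among non-focal
  species (uniformly, or with Lapointe–Garland phylogenetically constrained
  permutations where close relatives exchange status more readily, parameter
  `k`), the scenario is replayed, and the p-value is the proportion of
  permutations whose simulated rank (*Sim.*) is at or below *Obs.*
- **Missing-data completion** — species without a phylogenetic position are
  grafted at random into their family's subtree (edge chosen proportional to
  branch length, attachment uniform along the edge, tree kept ultrametric),
  and DD statuses are imputed by iterative random-forest imputation from
  taxonomy, body mass, and geographic range size. Replicate ensembles of
  completed data sets propagate the missing-data uncertainty.
- **A synthetic data generator** — Yule timetrees, liability-threshold
  statuses with controllable phylogenetic signal and focal-adjacent risk, and
  traits correlated with status — so the full pipeline is testable without
  any external downloads.

## Worked example

A five-species timetree in which the focal species `H` has one close relative
`X`, and `X` is critically endangered:

```r
library(phyloiso)

tr <- readNewick("((H:1,X:1):3,(Y:2,(Z:1,W:1):1):2);")
originalityTable(tr)
#>   species    ed_my rank
#> 1       H 2.500000  2.5
#> 2       X 2.500000  2.5
#> 3       Y 2.666667  1.0
#> 4       Z 2.166667  4.5
#> 5       W 2.166667  4.5

st <- data.frame(species = c("H","X","Y","Z","W"),
                 category = c("LC","CR","LC","LC","LC"))
monteCarloTest(tr, st, scenarioSpec("CR"), focal = "H",
               nPerm = 1000, seed = 42)
#> Monte Carlo originality-rank test for 'H'
#>   scenario: {CR} doomed, DD as_LC; 4/5 species survive
#>   scheme: uniform, 1000 permutations
#>   Obs. rank 1.0 | mean Sim. 2.61 (SD 1.01) | p = 0.244
```

Before any extinction, `H` shares rank 2.5 with its sister `X` (each has
2.5 MY of fair-proportion history; `Y`, on its long branch, is the most
original). Once the critically endangered `X` is pruned, `H` inherits their
whole shared stem and becomes the single most original survivor (*Obs.* = 1).
The Monte Carlo test then asks whether that gain is special to the observed
risk pattern: permuting the one CR label among the four non-focal species
gives a mean simulated rank of 2.61, and in 24% of permutations the focal
does at least as well — on five species, one doomed neighbor is not yet
statistically surprising.

Ensemble runs over completed data sets go through `runConfig()` /
`runFullAnalysis()`, which write a per-scenario summary table (`results.csv`),
per-replicate details, and a seed-stamped manifest. A thin command-line
wrapper lives in `inst/cli/phyloiso.R`.

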