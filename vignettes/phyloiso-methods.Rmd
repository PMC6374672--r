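---
title: "Originality under extinction scenarios: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Originality under extinction scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
originality statistic, the extinction scenarios and their null models, the
missing-data machinery, the synthetic data generator used for validation, and
every numerical decision a maintainer might want to revisit.

## The originality statistic

`phyloiso` measures how phylogenetically isolated a focal species becomes
when threatened species are removed from a timetree. The per-species score is
the evolutionary distinctiveness index (ED, the *fair proportion*): each edge
of length $L_b$ (million years, MY) is shared equally by its $n_b$ descendant
tips, and a tip accumulates $L_b / n_b$ along its root path. Two properties
make it attractive for this job: the scores sum exactly to the tree's total
branch length (so they partition phylogenetic diversity), and the score of a
survivor can only grow as relatives are pruned — each surviving edge keeps
its length while its tip count shrinks. Species are ranked from most
original (rank 1) downward, ties averaged.

Assumptions worth stating: the tree is rooted with branch lengths on every
edge; polytomies are legal and handled natively (no arbitrary resolution);
and a stem edge above the root, if present in the input, is dropped at
read time. A root stem subtends all $n$ tips and adds the same $L/n$ to
every score, so it can never change a rank; dropping it makes scores
comparable across differently-stemmed published trees.

One accounting subtlety follows from the stem convention. Pruning to a
survivor set $S$ whose most recent common ancestor sits below the original
root discards the edges above that ancestor — for the pruned tree they are a
root stem, contributing an equal `stem_length`$/|S|$ to every survivor.
`pruneTo()` therefore records the dropped length as an attribute, and the
ED-monotonicity property is asserted with that constant added back; ranks
are identical either way.

## Extinction scenarios and the Monte Carlo null

A scenario dooms one of the four nested category sets {CR}, {EN, CR},
{VU, EN, CR}, {NT, VU, EN, CR}; least-concern species are never doomed
(removing them would empty the tree). Data-deficient species are resolved
before pruning by one of three policies: the two bracketing extremes
(`as_LC`, `as_CR`) or imputation (below). After pruning, ED is *recomputed*
on the survivor tree — the focal's position in the tree of survivors — rather
than re-ranking pre-extinction scores; the latter remains available as
`recomputeED = FALSE` for sensitivity analyses, because the two differ
exactly when extinctions restructure who shares which edges.

The test statistic is the focal species' rank among survivors (*Obs.*). The
null hypothesis is that risk statuses are exchangeable across non-focal
species: statuses are permuted, the scenario replayed, and the simulated
rank (*Sim.*) recorded. The p-value is the plain proportion of permutations
with Sim. $\le$ Obs. The $(s+1)/(n+1)$ Monte Carlo correction is available
behind `correctedP = TRUE` but is off by default: the plug-in proportion is
the quantity the reporting convention (significance stars at 0.05 / 0.01 /
0.005) is defined over. The focal species keeps its own category in every
permutation, so it survives every replay by construction.

Two permutation schemes are provided:

* **uniform** — statuses are shuffled uniformly among non-focal species;
* **Lapointe–Garland** — statuses are reassigned sequentially in a freshly
  shuffled visiting order, each recipient drawing a not-yet-assigned status
  with probability proportional to
  $w_{ij} = (1 - d_{ij}/d_{\max})^{1/k}$,
  where $d_{ij}$ is patristic distance and $d_{\max}$ the largest
  tip-to-tip distance. At $k = 1$ permutations are strongly constrained by
  the phylogeny; as $k \to \infty$ all weights tend to 1. If a recipient's
  remaining donors all have zero weight the draw falls back to uniform among
  them (counted in `n_fallback`).

A caveat specific to timetrees: on an ultrametric tree every pair whose
common ancestor is the root sits exactly at $d_{\max} = 2 \times$ height, so
this weight form gives all cross-root pairs weight zero *at every finite
k* — statuses never cross the basal split, and the large-$k$ scheme does not
converge to the uniform one there. On trees with distinct pairwise distances
only the single maximal pair is frozen and the uniform limit holds, which is
where the package's limit checks run. Users comparing `k = 1` results
against the uniform scheme on a timetree should treat the basal freeze as
part of the null's definition, not a bug.

Tunable parameters, defaults, and reasons: `k = 1` (the strongest
phylogenetic constraint, the interesting extreme); `nPerm = 500` as a
single-data-set default, reduced to ~200 in replicate ensembles where the
ensemble supplies the averaging; the nominal level is 0.05 throughout.

## Missing data: grafting and imputation

Species with a known status but no phylogenetic position are grafted onto
the tree at random, constrained to the smallest monophyletic clade spanning
their family's placed members: an edge inside that clade is chosen with
probability proportional to its length and the attachment point is uniform
along the chosen edge, which together make the attachment density uniform
per unit of branch length — the most literal reading of
"proportional to branch length". The new pendant edge descends to the
present (length = age of the attachment point), preserving ultrametricity to
within 1e-6 MY. Insertion order is randomized and earlier grafts of the same
family are legitimate attachment targets for later ones — without that, the
order randomization would be a no-op. A family with a single placed member
degenerates to splitting that tip's pendant edge; a family with none falls
back to its order's subtree when the clade map links the family to an order,
and to the whole tree (with a warning) otherwise. Attachment is restricted
to edges *within* (below) the family ancestor, never its stem.

Data-deficient statuses are imputed in the missForest style: initialize
missing predictor cells by column median/mode and DD statuses by the global
mode, then iteratively refit a random forest per incomplete column on the
currently completed data and re-predict that column's originally missing
cells, stopping when the column-wise change first increases (keeping the
previous iterate) or after 10 rounds. Predictors are taxonomy (order,
family), log body mass, and log geographic range size. Two departures from
a plain missForest call are deliberate:

* the final DD category is *drawn from the forest's class-vote proportions*
  rather than taken as the majority vote (`draw = "sample"`, default), so
  repeated imputations across an ensemble express prediction uncertainty
  instead of collapsing to one answer; `draw = "mode"` restores the
  deterministic point prediction (and is what recovery-accuracy checks use);
* zero-variance predictors are dropped up front (a constant column carries
  no information, and the underlying forest code can stall on one), and if
  *no* informative predictor remains, DD categories are drawn from the
  observed status frequencies — the correct no-information behavior.

Factors with more than 53 levels are dropped from the predictor set (the
forest implementation's categorical limit) with a warning; in practice this
affects family-level taxonomy on large synthetic trees, where range size
carries the recoverable signal anyway.

Replicate ensembles (`buildReplicates()`) re-run grafting and imputation
independently per replicate, with replicate seeds derived deterministically
from one master seed, so an ensemble is reproducible end-to-end and
independent of execution order. Ensemble summaries pool replicate p-values
by averaging (`mean_p`, default) — with equal permutation counts this equals
pooling the indicator draws — or by comparing the pooled simulated ranks
against the mean observed rank (`pooled_sims`); the choice is exposed
because no single pooling rule is canonical for replicate-completed data.

## The synthetic generator

The generator exists so that every stage — scoring, scenarios, permutation
nulls, grafting, imputation, ensembles — can be validated without external
downloads. It emulates the *statistical shape* of a Red-List-annotated
timetree:

* **Trees**: forward pure-birth (Yule) simulation stopped at `nTips`
  lineages (`birthRate` per MY, default 0.05, giving heights of tens of MY
  at the default sizes). Pendant edges are snapped to the exact common
  height, removing floating-point drift at the present.
* **Statuses**: a liability-threshold model. The latent risk is
  $z_i = \sqrt{w}\,\mathrm{BM}_i + \sqrt{1-w}\,\varepsilon_i
  + \beta e^{-d(i,\mathrm{focal})/h}$, with BM a standardized Brownian value
  (phylogenetic signal, weight $w \in [0,1]$), $\varepsilon$ iid normal, and
  the $\beta$ term planting elevated risk among the focal's close relatives
  ($h$ = tree height). Categories are assigned by slicing the $z$ order at
  prevalence quantiles, so realized frequencies match the prevalences
  exactly up to rounding — for any $w$ or $\beta$. The focal is then forced
  to LC (a secure focal taxon that survives every scenario) and non-focal
  species are flagged DD by independent coin flips. Default prevalences
  (LC .63, NT .07, VU .11, EN .13, CR .06; DD fraction .05) loosely mimic a
  large mammal assessment and are documented conveniences, not estimates.
* **Traits**: families and orders are clades cut at 25% and 60% of tree
  height; log body mass is Brownian; log range size is linear in the ordinal
  status code with slope $-b$ plus noise, planting the negative
  range-size–risk association the imputation is meant to recover. A
  configurable fraction of mass/range cells (never taxonomy) is blanked.
* **Fixtures**: a configurable fraction of non-focal tips is withheld from
  the tree into a placement table; their true positions stay available in
  the full tree for recovery checks.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: realistic diversification (no extinction, no
rate shifts), non-monophyletic taxonomy, the Red List's criteria structure
(statuses here derive from a single latent axis), correlated assessment
effort, or body-mass-dependent risk. Conclusions about real taxa need the
real inputs; the synthetic results validate the machinery, not the biology.

## Numerical choices

* **Tie detection.** ED values reach ranking through a fixed 1e-9 MY grid
  (`round(ed / 1e-9)`): structural ties (a cherry's two tips) produce sums
  of the same shares in different association orders across the package's
  two scoring routes — explicit pruning versus the incidence-matrix
  permutation engine — and differ in the last ulp. Exact-equality ties would
  make the routes disagree on ranks; nanoyear rounding makes them identical
  while leaving any real branch-length difference intact. Near-ties closer
  than 1e-9 MY are merged by construction.
* **The permutation engine.** For repeated permutations on one fixed tree,
  scenario ranks are computed as two matrix–vector products against a
  precomputed edge-by-tip incidence matrix (survivor counts per edge, then
  masked share sums), restricted to edges strictly below the survivors'
  common ancestor — algebraically identical to prune-and-rescore, and tested
  against it. Trees beyond 2000 tips fall back to explicit pruning to bound
  memory.
* **Tolerances.** Ultrametricity uses an absolute 1e-6 MY criterion (drift
  is bounded in time units, not relative to height); graft bookkeeping and
  distance-preservation checks use the same scale; Newick output carries 17
  significant digits so write/read round-trips are exact.
* **Degenerate inputs.** Single-tip trees error unless explicitly allowed;
  a prevalence vector concentrated on one category is legal; zero-length
  edges are legal graft targets with probability zero; an all-DD status
  table is an error (nothing to learn from); a scenario that dooms the focal
  raises an explicit focal-extinct error, which ensemble runs record per
  scenario and survive.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen to give the statistical
assertions room without inflating runtimes: conservation and monotonicity on
100 random trees (50 and 8–30 tips); null calibration on 200 data sets of 60
tips with 199 permutations; planted-effect power ($\beta = 8$) on 100 data
sets of 100 tips; the exhaustive-enumeration comparison at 10,000
permutations on a 4-tip tree; 10,000 single-tip grafts for the
placement-frequency test; imputation recovery on 500 species with 20% DD;
and the ensemble bookkeeping run with two 30-tip core trees, 200 replicates
each, 4 scenarios and 200 permutations (400 completed data sets; 320,000
simulated originality vectors, counted in the manifest).

## Known limitations

The Lapointe–Garland weight transform is one reasonable functional form
matching the documented $k$ limits, not a verified reproduction of the
original publication's transform; the basal-freeze behavior on ultrametric
trees discussed above is a property of this form. Imputation draws are
conditionally independent across species given the fitted forest (no joint
draw). Grafting assigns positions at random within the family clade — it is
a sensitivity device for topological uncertainty, not probabilistic
placement from data. And ED itself divides history equally among
descendants; other originality indices (equal-splits, Shapley) are out of
scope.
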