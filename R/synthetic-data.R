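#' Configuration for the synthetic data generator
#'
#' Bundles every knob of the generator with documented defaults. The default
#' category prevalences loosely mimic the composition of a large mammal risk
#' assessment (63% LC, 7% NT, 11% VU, 13% EN, 6% CR among non-DD species,
#' plus a 5% chance of being data deficient); they are convenient defaults,
#' not estimates.
#'
#' @param nTips number of species (>= 3).
#' @param birthRate Yule speciation rate per MY (default 0.05, giving tree
#'   heights of tens of MY at the default size, a timetree-like scale).
#' @param prevalences named proportions over `LC, NT, VU, EN, CR`, summing
#'   to 1.
#' @param ddFraction probability that a (non-focal) species is flagged DD.
#' @param w phylogenetic-signal weight of the risk liability, in `[0, 1]`:
#'   0 = independent risks, 1 = fully Brownian risks.
#' @param beta focal-adjacent risk boost (>= 0): liability of species `i`
#'   gains `beta * exp(-d(i, focal) / h)` with `h` the tree height, planting
#'   elevated risk among the focal species' close relatives.
#' @param fractionUnplaced fraction of non-focal tips withheld from the tree
#'   into a placement table, in `[0, 1)`.
#' @param traitEffects list with `logMassSigma` (Brownian rate of log body
#'   mass), `a` (log range intercept), `b` (ordinal-status slope of log
#'   range; larger = stronger planted range-size signal), `sigma` (residual
#'   SD of log range).
#' @param missingTraitFrac fraction of mass/range cells blanked at random.
#' @param seed master seed.
#' @return an object of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nTips = 100L, birthRate = 0.05,
                            prevalences = c(LC = 0.63, NT = 0.07, VU = 0.11,
                                            EN = 0.13, CR = 0.06),
                            ddFraction = 0.05, w = 0.3, beta = 0,
                            fractionUnplaced = 0,
                            traitEffects = list(logMassSigma = 0.15, a = 12,
                                                b = 1, sigma = 1),
                            missingTraitFrac = 0.1, seed = 1L) {
  stopifnot(nTips >= 3L, birthRate > 0, w >= 0, w <= 1, beta >= 0,
            fractionUnplaced >= 0, fractionUnplaced < 1,
            ddFraction >= 0, ddFraction < 1)
  if (!identical(names(prevalences), IUCN_CATEGORIES))
    stop("'prevalences' must be named ", paste(IUCN_CATEGORIES, collapse = ", "))
  if (abs(sum(prevalences) - 1) > 1e-9)
    stop("prevalences must sum to 1")
  structure(list(nTips = as.integer(nTips), birthRate = birthRate,
                 prevalences = prevalences, ddFraction = ddFraction, w = w,
                 beta = beta, fractionUnplaced = fractionUnplaced,
                 traitEffects = traitEffects,
                 missingTraitFrac = missingTraitFrac, seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Simulate an ultrametric Yule timetree
#'
#' Forward pure-birth simulation stopped at `nTips` extant lineages, so the
#' lineage count through time follows Yule expectations. Tips are labeled
#' `sp0001, sp0002, ...`; heights are in MY for a per-MY `birthRate`.
#'
#' @param nTips number of tips (>= 3).
#' @param birthRate speciation rate per lineage per MY.
#' @param seed optional RNG seed (same seed, same Newick string).
#' @return an ultrametric `phylo` object.
#' @export
simulateTree <- function(nTips, birthRate = 0.05, seed = NULL) {
  if (nTips < 3L) stop("'nTips' must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- phytools::pbtree(b = birthRate, d = 0, n = nTips, type = "continuous",
                         quiet = TRUE)
  tr$tip.label <- sprintf("sp%04d", seq_len(ape::Ntip(tr)))
  tr$root.edge <- NULL
  ## snap out floating-point drift so all tips sit exactly at the present
  depth <- .nodeDepths(tr)[seq_len(nTips)]
  pend <- match(seq_len(nTips), tr$edge[, 2L])
  tr$edge.length[pend] <- tr$edge.length[pend] + (max(depth) - depth)
  .assertPhylo(tr)
  tr
}

#' Simulate risk statuses with tunable phylogenetic structure
#'
#' Liability-threshold model: each species' latent risk is
#' `z_i = sqrt(w) * BM_i + sqrt(1 - w) * eps_i + beta * exp(-d(i, focal)/h)`,
#' where `BM` is a unit-rate Brownian value standardized across tips, `eps`
#' is iid standard normal, `d` the patristic distance to the focal tip and
#' `h` the tree height. Categories are assigned by slicing the `z` order at
#' the prevalence quantiles (higher liability, higher risk), so realized
#' frequencies honor the prevalences exactly up to integer rounding. The
#' focal species is then forced to LC (mirroring a secure focal taxon and
#' guaranteeing it survives every scenario), and each non-focal species is
#' independently flagged DD with probability `ddFraction`, hiding its
#' category.
#'
#' @param tree a `phylo` object.
#' @param prevalences named proportions over `LC..CR` summing to 1.
#' @param w phylogenetic-signal weight in `[0, 1]`.
#' @param beta focal-adjacent risk boost (>= 0).
#' @param focal focal tip label.
#' @param ddFraction DD flag probability (default 0).
#' @param seed optional RNG seed.
#' @return a status table; attribute `true_category` keeps the pre-DD
#'   categories (used to validate imputation).
#' @export
simulateStatuses <- function(tree, prevalences = c(LC = 0.63, NT = 0.07,
                                                   VU = 0.11, EN = 0.13,
                                                   CR = 0.06),
                             w = 0, beta = 0, focal = tree$tip.label[1],
                             ddFraction = 0, seed = NULL) {
  .assertPhylo(tree)
  stopifnot(w >= 0, w <= 1, beta >= 0)
  if (abs(sum(prevalences) - 1) > 1e-9) stop("prevalences must sum to 1")
  if (!focal %in% tree$tip.label) stop("focal not a tip of the tree")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)

  bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  bm <- (bm - mean(bm)) / max(stats::sd(bm), .Machine$double.eps)
  eps <- stats::rnorm(n)
  z <- sqrt(w) * bm + sqrt(1 - w) * eps
  if (beta > 0) {
    d <- patristicMatrix(tree)[, focal]
    z <- z + beta * exp(-d[tree$tip.label] / treeHeight(tree))
  }

  bounds <- round(cumsum(prevalences) * n)
  counts <- diff(c(0L, bounds))
  counts[length(counts)] <- n - sum(counts[-length(counts)])
  cat <- rep(IUCN_CATEGORIES, times = counts)
  ord <- order(z)  # ascending liability -> ascending risk
  category <- character(n)
  category[ord] <- cat
  names(category) <- tree$tip.label

  trueCategory <- category
  trueCategory[focal] <- "LC"
  category <- trueCategory
  if (ddFraction > 0) {
    dd <- stats::runif(n) < ddFraction & tree$tip.label != focal
    category[dd] <- "DD"
  }
  out <- data.frame(species = tree$tip.label, category = unname(category),
                    stringsAsFactors = FALSE)
  attr(out, "true_category") <- data.frame(species = tree$tip.label,
                                           category = unname(trueCategory),
                                           stringsAsFactors = FALSE)
  out
}

## Cut the tree at `age` MY before the present; every edge crossing that age
## defines a clade containing the tips below it.
.cutClades <- function(tree, age) {
  ages <- .nodeAges(tree)
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- tree$edge[1L, 1L]
  vapply(seq_len(n), function(tip) {
    node <- tip
    while (parent[node] != 0 && ages[parent[node]] < age) node <- parent[node]
    node
  }, integer(1))
}

#' Simulate taxonomy and traits correlated with risk status
#'
#' Families (and orders) are the clades obtained by cutting the tree at a
#' configurable age; log body mass evolves as Brownian motion on the tree;
#' log geographic range size decreases linearly with the ordinal risk code
#' (`log range = a - b * ordinal + noise`), planting the negative
#' range-size/risk association the imputation step is meant to recover. A
#' fraction of mass/range cells (never taxonomy) is blanked at random.
#'
#' @param tree a `phylo` object.
#' @param statuses a status table from [simulateStatuses()]; DD species use
#'   their hidden true category when available so traits remain informative
#'   about the category to be recovered.
#' @param effects list with `logMassSigma`, `a`, `b`, `sigma` (see
#'   [syntheticConfig()]).
#' @param familyAge,orderAge cut ages in MY (defaults: 25% and 60% of tree
#'   height).
#' @param missingFrac fraction of mass/range cells blanked.
#' @param seed optional RNG seed.
#' @return a trait table: `species`, `order`, `family`, `body_mass_g`,
#'   `range_km2`.
#' @export
simulateTraits <- function(tree, statuses,
                           effects = list(logMassSigma = 0.15, a = 12, b = 1,
                                          sigma = 1),
                           familyAge = NULL, orderAge = NULL,
                           missingFrac = 0, seed = NULL) {
  .assertPhylo(tree)
  .assertStatusTable(statuses)
  if (!is.null(seed)) set.seed(seed)
  h <- treeHeight(tree)
  if (is.null(familyAge)) familyAge <- 0.25 * h
  if (is.null(orderAge)) orderAge <- 0.60 * h

  famNode <- .cutClades(tree, familyAge)
  ordNode <- .cutClades(tree, orderAge)
  family <- sprintf("f%03d", match(famNode, sort(unique(famNode))))
  ord <- sprintf("o%02d", match(ordNode, sort(unique(ordNode))))

  logMass <- ape::rTraitCont(tree, model = "BM",
                             sigma = effects$logMassSigma, root.value = 8)
  truth <- attr(statuses, "true_category")
  cat <- if (!is.null(truth)) truth$category[match(tree$tip.label, truth$species)]
         else statuses$category[match(tree$tip.label, statuses$species)]
  ordinal <- statusOrdinal(cat)
  ordinal[is.na(ordinal)] <- 2L  # DD without recorded truth: mid-scale
  logRange <- effects$a - effects$b * ordinal +
    stats::rnorm(ape::Ntip(tree), 0, effects$sigma)

  out <- data.frame(species = tree$tip.label, order = ord, family = family,
                    body_mass_g = exp(logMass[tree$tip.label]),
                    range_km2 = exp(logRange), stringsAsFactors = FALSE)
  if (missingFrac > 0) {
    for (cn in c("body_mass_g", "range_km2")) {
      blank <- stats::runif(nrow(out)) < missingFrac
      out[[cn]][blank] <- NA_real_
    }
  }
  out
}

#' Generate a complete synthetic analysis fixture
#'
#' Simulates a tree, statuses and traits under one [syntheticConfig()],
#' designates a focal tip, and withholds the configured fraction of non-focal
#' tips from the tree into a placement table (their true positions remain in
#' `fullTree` for recovery checks).
#'
#' @param config a [syntheticConfig()].
#' @return a list: `tree` (with unplaced tips removed), `fullTree`,
#'   `statuses`, `traits`, `placements`, `clades`, `focal`, `config`.
#' @export
makeFixture <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, 5L)

  full <- simulateTree(config$nTips, config$birthRate, seed = seeds[1])
  set.seed(seeds[2])
  focal <- sample(full$tip.label, 1L)
  statuses <- simulateStatuses(full, config$prevalences, config$w, config$beta,
                               focal, config$ddFraction, seed = seeds[3])
  traits <- simulateTraits(full, statuses, config$traitEffects,
                           missingFrac = config$missingTraitFrac,
                           seed = seeds[4])

  set.seed(seeds[5])
  nHide <- floor(config$fractionUnplaced * config$nTips)
  hidden <- character(0)
  if (nHide > 0) {
    pool <- setdiff(full$tip.label, focal)
    hidden <- sample(pool, min(nHide, length(pool) - 1L))
  }
  placements <- data.frame(species = hidden,
                           family = traits$family[match(hidden, traits$species)],
                           stringsAsFactors = FALSE)
  tree <- if (length(hidden)) pruneTo(full, setdiff(full$tip.label, hidden))
          else full
  list(tree = tree, fullTree = full, statuses = statuses, traits = traits,
       placements = placements,
       clades = traits[, c("species", "order", "family")],
       focal = focal, config = config)
}

#' Write a fixture's files (Newick tree plus CSV tables)
#'
#' @param fixture a fixture from [makeFixture()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeNewick(fixture$tree, file.path(dir, "tree.nwk"))
  writeStatusCsv(fixture$statuses, file.path(dir, "statuses.csv"))
  utils::write.csv(fixture$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(fixture$placements, file.path(dir, "placements.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(focal = fixture$focal,
                            seed = fixture$config$seed,
                            true_placements = fixture$placements$species),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a fixture directory written by [writeFixture()]
#' @param dir fixture directory.
#' @return a list with `tree`, `statuses`, `traits`, `placements`, `focal`.
#' @export
readFixture <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  list(tree = readNewick(file.path(dir, "tree.nwk")),
       statuses = readStatusCsv(file.path(dir, "statuses.csv")),
       traits = utils::read.csv(file.path(dir, "traits.csv"),
                                stringsAsFactors = FALSE),
       placements = utils::read.csv(file.path(dir, "placements.csv"),
                                    stringsAsFactors = FALSE,
                                    colClasses = "character"),
       focal = man$focal)
}
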