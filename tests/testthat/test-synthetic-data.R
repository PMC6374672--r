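test_that("simulated Yule trees are ultrametric, labeled and reproducible", {
  tr <- simulateTree(50, birthRate = 0.1, seed = 41)
  expect_equal(ape::Ntip(tr), 50)
  expect_true(isUltrametric(tr, 1e-9))
  expect_equal(tr$tip.label[1], "sp0001")
  expect_equal(writeNewick(simulateTree(50, 0.1, seed = 41)), writeNewick(tr))
  expect_false(writeNewick(simulateTree(50, 0.1, seed = 42)) == writeNewick(tr))
  expect_error(simulateTree(2), ">= 3")
})

test_that("lineage counts grow at the pure-birth exponential rate", {
  # E[N(t)] = 2 e^(lambda t) from the two root lineages, well before the
  # stopping size is reached
  lambda <- 0.1
  t <- log(5) / lambda  # expected 10 lineages, stop at 40
  counts <- vapply(1:300, function(i) {
    tr <- simulateTree(40, birthRate = lambda, seed = 4000 + i)
    ages <- phyloiso:::.nodeAges(tr)
    h <- treeHeight(tr)
    nodes <- ages[-(1:40)]  # internal node ages
    if (h <= t) return(NA_real_)
    1 + sum(h - nodes <= t)
  }, numeric(1))
  counts <- counts[!is.na(counts)]
  expect_gt(length(counts), 250)
  expect_lt(abs(mean(counts) - 10) / 10, 0.1)
})

test_that("status generation honors prevalences exactly and plants signal", {
  tr <- simulateTree(47, seed = 43)
  # degenerate prevalence vector: everyone least concern
  allLC <- simulateStatuses(tr, c(LC = 1, NT = 0, VU = 0, EN = 0, CR = 0),
                            seed = 44)
  expect_true(all(allLC$category == "LC"))

  # realized frequencies match the prevalence quantiles up to rounding
  # (the focal is forced LC afterwards, shifting at most one species)
  prev <- c(LC = 0.4, NT = 0.2, VU = 0.2, EN = 0.1, CR = 0.1)
  st <- simulateStatuses(tr, prev, w = 0.5, focal = "sp0001", seed = 45)
  counts <- table(factor(st$category, levels = IUCN_CATEGORIES))
  target <- diff(c(0, round(cumsum(prev) * 47)))
  expect_true(all(abs(counts - target) <= 1))

  # the focal is always LC, DD flags appear at about the configured rate
  stDD <- simulateStatuses(tr, prev, focal = "sp0005", ddFraction = 0.3,
                           seed = 46)
  expect_equal(stDD$category[stDD$species == "sp0005"], "LC")
  expect_gt(sum(stDD$category == "DD"), 4)
  truth <- attr(stDD, "true_category")
  expect_false(any(truth$category == "DD"))

  # phylogenetic signal: sister tips agree more under w = 1 than w = 0
  diffs <- vapply(1:300, function(i) {
    tr <- simulateTree(30, seed = 5000 + i)
    cherryParents <- names(which(table(tr$edge[, 1][tr$edge[, 2] <= 30]) == 2))
    pairs <- lapply(cherryParents, function(p)
      tr$tip.label[tr$edge[tr$edge[, 1] == as.integer(p), 2]])
    pairs <- Filter(function(x) length(x) == 2, pairs)
    if (!length(pairs)) return(c(NA, NA))
    s1 <- simulateStatuses(tr, w = 1, seed = 6000 + i)
    s0 <- simulateStatuses(tr, w = 0, seed = 6000 + i)
    gap <- function(st) {
      o <- stats::setNames(statusOrdinal(st$category), st$species)
      mean(vapply(pairs, function(p) abs(o[p[1]] - o[p[2]]), numeric(1)))
    }
    c(gap(s1), gap(s0))
  }, numeric(2))
  ok <- colSums(is.na(diffs)) == 0
  tst <- stats::t.test(diffs[1, ok], diffs[2, ok], paired = TRUE,
                       alternative = "less")
  expect_lt(tst$p.value, 0.01)
})

test_that("trait generation plants the configured range-size effect", {
  tr <- simulateTree(500, seed = 47)
  # balanced prevalences: status ties would otherwise cap attainable |rho|
  st <- simulateStatuses(tr, prevalences = c(LC = 0.2, NT = 0.2, VU = 0.2,
                                             EN = 0.2, CR = 0.2),
                         w = 0, seed = 48)
  ords <- statusOrdinal(attr(st, "true_category")$category)

  # b = 0: no association between range and status
  t0 <- simulateTraits(tr, st, effects = list(logMassSigma = 0.15, a = 12,
                                              b = 0, sigma = 1), seed = 49)
  expect_lt(abs(stats::cor(log(t0$range_km2), ords)), 0.1)

  # strong monotone effect with little noise
  t1 <- simulateTraits(tr, st, effects = list(logMassSigma = 0.15, a = 12,
                                              b = 3, sigma = 0.1), seed = 50)
  rho <- stats::cor(log(t1$range_km2), ords, method = "spearman")
  expect_lt(rho, -0.9)

  # taxonomy is complete and matches the clade cut
  expect_true(all(nzchar(t1$family)))
  expect_true(all(nzchar(t1$order)))
  fam <- phyloiso:::.cutClades(tr, 0.25 * treeHeight(tr))
  expect_equal(length(unique(t1$family)), length(unique(fam)))

  # missing fraction blanks mass/range but never taxonomy
  t2 <- simulateTraits(tr, st, missingFrac = 0.3, seed = 51)
  expect_gt(sum(is.na(t2$body_mass_g)), 0)
  expect_false(anyNA(t2$family))
})

test_that("fixtures are internally consistent and round-trip through files", {
  fx0 <- makeFixture(syntheticConfig(nTips = 30, fractionUnplaced = 0,
                                     seed = 52))
  expect_equal(nrow(fx0$placements), 0)
  expect_equal(ape::Ntip(fx0$tree), 30)

  fx <- makeFixture(syntheticConfig(nTips = 40, fractionUnplaced = 0.2,
                                    ddFraction = 0.1, seed = 53))
  expect_equal(nrow(fx$placements), 8)
  expect_equal(ape::Ntip(fx$tree), 32)
  expect_true(fx$focal %in% fx$tree$tip.label)
  # withheld species keep their true positions in the full tree
  expect_true(all(fx$placements$species %in% fx$fullTree$tip.label))

  dir <- tempfile()
  writeFixture(fx, dir)
  back <- readFixture(dir)
  expect_equal(back$focal, fx$focal)
  expect_equal(back$statuses$species, fx$statuses$species)
  expect_equal(back$statuses$category, fx$statuses$category)
  expect_equal(sort(back$placements$species), sort(fx$placements$species))
  d0 <- patristicMatrix(fx$tree)
  expect_equal(patristicMatrix(back$tree)[rownames(d0), colnames(d0)], d0,
               tolerance = 1e-9)

  # identical seeds reproduce the fixture exactly
  fx2 <- makeFixture(syntheticConfig(nTips = 40, fractionUnplaced = 0.2,
                                     ddFraction = 0.1, seed = 53))
  expect_identical(fx2$statuses, fx$statuses)
  expect_equal(writeNewick(fx2$fullTree), writeNewick(fx$fullTree))
})
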