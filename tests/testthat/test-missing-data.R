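test_that("grafting handles the degenerate and identity cases", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  clades <- data.frame(species = c("A", "B", "C"),
                       family = c("f1", "f1", "f2"))

  # empty placement table: tree unchanged
  same <- graftRandomTips(tr, data.frame(species = character(0),
                                         family = character(0)), clades)
  expect_equal(ape::Ntip(same), 3)

  # a single-member family degenerates to splitting that tip's pendant edge
  set.seed(21)
  g <- graftRandomTips(tr, data.frame(species = "Cnew", family = "f2"), clades)
  expect_equal(ape::Ntip(g), 4)
  log <- attr(g, "graft_log")
  expect_equal(log$edge_tips, "C")
  expect_true(isUltrametric(g, 1e-9))
  # new tip forms a cherry with C, below C's pendant edge
  dg <- patristicMatrix(g)
  expect_lt(dg["C", "Cnew"], dg["C", "A"])

  # grafting a species already in the tree is refused
  expect_error(graftRandomTips(tr, data.frame(species = "A", family = "f1"),
                               clades), "already placed")
  # non-ultrametric trees are refused
  bad <- readNewick("((A:1,B:2):1,C:2);")
  expect_error(graftRandomTips(bad, data.frame(species = "X", family = "f1"),
                               clades), "ultrametric")
})

test_that("grafting preserves existing structure and stays ultrametric", {
  fx <- makeFixture(syntheticConfig(nTips = 40, fractionUnplaced = 0.15,
                                    ddFraction = 0, missingTraitFrac = 0,
                                    seed = 22))
  expect_gt(nrow(fx$placements), 2)
  d0 <- patristicMatrix(fx$tree)
  len0 <- totalBranchLength(fx$tree)
  set.seed(23)
  g <- graftRandomTips(fx$tree, fx$placements, fx$clades)
  expect_equal(ape::Ntip(g), ape::Ntip(fx$tree) + nrow(fx$placements))
  expect_true(isUltrametric(g, 1e-6))
  # pre-existing pairwise distances are untouched (up to fp noise in MY)
  d1 <- patristicMatrix(g)[rownames(d0), colnames(d0)]
  expect_lt(max(abs(d1 - d0)), 1e-6)
  # total length grows by exactly the sum of new pendant lengths
  log <- attr(g, "graft_log")
  expect_equal(totalBranchLength(g), len0 + sum(log$pendant_length),
               tolerance = 1e-9)
  # every graft stayed inside its family (no fallback needed here)
  expect_true(all(log$fallback == "none"))
})

test_that("grafting falls back to order then root for unplaced families", {
  tr <- simulateTree(10, seed = 24)
  clades <- data.frame(species = tr$tip.label,
                       family = rep(c("f1", "f2"), 5),
                       order = rep("o1", 10))
  set.seed(25)
  # family f9 has no placed tip, but the clade map ties it to order o1
  clades9 <- rbind(clades, data.frame(species = "Z9", family = "f9",
                                      order = "o1"))
  g <- graftRandomTips(tr, data.frame(species = "X", family = "f9"), clades9)
  expect_equal(attr(g, "graft_log")$fallback, "order")
  expect_true(isUltrametric(g, 1e-6))
  # without an order to fall back on, graft below the root with a warning
  expect_warning(
    g2 <- graftRandomTips(tr, data.frame(species = "Y", family = "f9"),
                          clades[, c("species", "family")]),
    "no placed member")
  expect_equal(attr(g2, "graft_log")$fallback, "root")
})

test_that("imputation completes DD statuses without touching the rest", {
  fx <- makeFixture(syntheticConfig(nTips = 60, ddFraction = 0.2,
                                    missingTraitFrac = 0.1, seed = 26))
  dd <- fx$statuses$category == "DD"
  expect_gt(sum(dd), 3)
  imp <- imputeStatuses(fx$traits, fx$statuses, seed = 27)
  expect_false(any(imp$category == "DD"))
  expect_equal(imp$category[!dd], fx$statuses$category[!dd])
  expect_true(all(imp$category[dd] %in% IUCN_CATEGORIES))
  expect_gte(attr(imp, "iterations"), 1)

  # no DD: identity
  clean <- data.frame(species = c("A", "B"), category = c("LC", "EN"))
  expect_identical(imputeStatuses(fx$traits, clean), clean)

  # all DD: nothing to learn from
  allDD <- data.frame(species = fx$statuses$species,
                      category = rep("DD", nrow(fx$statuses)))
  expect_error(imputeStatuses(fx$traits, allDD), "all species")
})

test_that("uninformative predictors yield frequency-matched imputations", {
  set.seed(28)
  n <- 1000
  cats <- sample(c("LC", "EN", "CR"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  st <- data.frame(species = paste0("s", 1:n), category = cats)
  ddIdx <- sample(n, 300)
  st$category[ddIdx] <- "DD"
  traits <- data.frame(species = st$species, body_mass_g = 100,
                       range_km2 = 10)
  imp <- suppressWarnings(imputeStatuses(traits, st, seed = 29))
  obsFreq <- prop.table(table(factor(st$category[-ddIdx],
                                     levels = c("LC", "EN", "CR"))))
  impFreq <- prop.table(table(factor(imp$category[ddIdx],
                                     levels = c("LC", "EN", "CR"))))
  expect_lt(max(abs(impFreq - obsFreq)), 0.1)
})

test_that("a planted trait signal is recovered well above the mode baseline", {
  fx <- makeFixture(syntheticConfig(
    nTips = 200, ddFraction = 0.2, missingTraitFrac = 0,
    traitEffects = list(logMassSigma = 0.15, a = 12, b = 2, sigma = 0.1),
    seed = 30))
  truth <- attr(fx$statuses, "true_category")
  dd <- which(fx$statuses$category == "DD")
  imp <- imputeStatuses(fx$traits, fx$statuses, seed = 31)
  acc <- mean(imp$category[dd] == truth$category[dd])
  mode <- names(which.max(table(fx$statuses$category[-dd])))
  base <- mean(truth$category[dd] == mode)
  expect_gt(acc, base)
  expect_gt(acc, 0.7)
})

test_that("replicate ensembles have the right size, seeds and content", {
  tr1 <- simulateTree(20, seed = 32)
  tr2 <- simulateTree(20, seed = 33)
  st <- simulateStatuses(tr1, seed = 34)

  ens <- buildReplicates(list(tr1, tr2), st, nRep = 3, seed = 35)
  expect_length(ens, 6)
  man <- attr(ens, "manifest")
  expect_equal(nrow(man), 6)
  expect_equal(man$tree, rep(1:2, each = 3))
  expect_equal(anyDuplicated(man$seed), 0)

  # manifest-only mode matches the materialized bookkeeping
  man2 <- buildReplicates(list(tr1, tr2), st, nRep = 3, seed = 35,
                          materialize = FALSE)
  expect_identical(man, man2)

  # nRep = 1, nothing missing: the single input data set unchanged
  one <- buildReplicates(tr1, st, nRep = 1, seed = 36)
  expect_length(one, 1)
  expect_identical(one[[1]]$statuses, st)
  expect_equal(writeNewick(one[[1]]$tree), writeNewick(tr1))

  med <- ensembleMedianED(one)
  ref <- computeED(tr1)
  expect_equal(med$median_ed[match(ref$species, med$species)], ref$ed_my)
})
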