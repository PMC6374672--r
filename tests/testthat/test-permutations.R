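test_that("uniform permutation conserves categories and fixes the focal", {
  st <- data.frame(species = c("F", "A", "B", "C"),
                   category = c("LC", "CR", "EN", "VU"))
  set.seed(1)
  for (i in 1:50) {
    p <- permuteUniform(st, "F")
    expect_equal(sort(p$category), sort(st$category))
    expect_equal(p$category[p$species == "F"], "LC")
  }
  expect_error(permuteUniform(st, "nope"), "not in")

  # all 6 arrangements of 3 non-focal statuses are equally likely
  set.seed(2)
  draws <- replicate(10000, paste(permuteUniform(st, "F")$category[-1],
                                  collapse = ""))
  freq <- table(draws) / 10000
  expect_equal(length(freq), 6)
  se <- sqrt((1 / 6) * (5 / 6) / 10000)
  expect_true(all(abs(freq - 1 / 6) < 3 * se))
})

test_that("exchange weights follow (1 - d/dmax)^(1/k) with the right limits", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  d <- patristicMatrix(tr)
  w <- lgWeights(d, k = 1)
  expect_equal(unname(w["A", "B"]), 0.5)
  expect_equal(unname(w["A", "C"]), 0)
  expect_equal(unname(w["A", "A"]), 1)

  # k -> infinity gives the uniform limit
  wInf <- lgWeights(d, k = Inf)
  expect_true(all(wInf == 1))

  # weights are symmetric and within [0, 1] on random trees
  for (i in 1:20) {
    tr <- randomTree(sample(5:25, 1), seed = 1100 + i)
    w <- lgWeights(patristicMatrix(tr), k = sample(c(1, 2, 10), 1))
    expect_equal(w, t(w))
    expect_true(all(w >= 0 & w <= 1))
  }

  expect_error(lgWeights(matrix(0, 3, 3), 1), "zero")
  expect_error(lgWeights(patristicMatrix(tr), 0.5), "k >= 1")
})

test_that("constrained permutation conserves categories and respects weights", {
  # A and B are each other's neighbors; C sits at maximal distance from both
  tr <- readNewick("((A:1,B:1):3,(C:1,F:1):3);")
  st <- data.frame(species = c("A", "B", "C", "F"),
                   category = c("EN", "VU", "CR", "LC"))
  set.seed(3)
  for (i in 1:500) {
    p <- permuteLG(st, tr, k = 1, "F")
    expect_equal(sort(p$category), sort(st$category))
    expect_equal(p$category[p$species == "F"], "LC")
    # w(A,C) = w(B,C) = 0 at k=1: C's CR can never migrate to A or B
    expect_equal(p$category[p$species == "C"], "CR")
    expect_equal(attr(p, "n_fallback"), 0L)
  }

  # very large k approaches the uniform arrangement distribution; the one
  # zero-weight pair (at the maximal distance) involves the focal here, so
  # the non-focal arrangement distribution is free to become uniform
  trF <- readNewick("(((A:1,B:1):1,C:2.5):1.5,F:4);")
  stF <- data.frame(species = c("A", "B", "C", "F"),
                    category = c("EN", "VU", "CR", "LC"))
  set.seed(4)
  drawsLG <- replicate(30000,
                       paste(permuteLG(stF, trF, k = 1e6, "F")$category[1:3],
                             collapse = ""))
  fLG <- table(factor(drawsLG, levels = names(table(drawsLG)))) / 30000
  tv <- sum(abs(fLG - 1 / 6)) / 2
  expect_equal(length(fLG), 6)
  expect_lt(tv, 0.02)
})

test_that("Monte Carlo p-value is the proportion of Sim at or below Obs", {
  expect_equal(phyloiso:::.mc_p(c(3, 1, 2, 5), 2), 0.5)
  expect_equal(phyloiso:::.mc_p(c(3, 4, 5), 2), 0)
  expect_equal(phyloiso:::.mc_p(c(1, 1, 2), 2), 1)
  expect_equal(phyloiso:::.mc_p(c(3, 1, 2, 5), 2, corrected = TRUE), 3 / 5)
})

test_that("significance codes follow the reporting bins", {
  expect_equal(significanceCode(0.03), "*")
  expect_equal(significanceCode(0.007), "**")
  expect_equal(significanceCode(0.004), "***")
  expect_equal(significanceCode(0.5), "")
  expect_equal(significanceCode(c(0.05, 0.01, 0.005)), c("*", "**", "***"))
  expect_error(significanceCode(1.2))
})

test_that("tests are reproducible and the focal always survives", {
  tr <- simulateTree(25, seed = 11)
  st <- simulateStatuses(tr, w = 0.3, focal = "sp0003", seed = 12)
  spec <- scenarioSpec("VU")
  a <- monteCarloTest(tr, st, spec, "sp0003", nPerm = 100, seed = 99)
  b <- monteCarloTest(tr, st, spec, "sp0003", nPerm = 100, seed = 99)
  expect_identical(a$obs, b$obs)
  expect_identical(a$sim, b$sim)
  expect_identical(a$p, b$p)
  expect_true(a$p >= 0 && a$p <= 1)
  expect_equal(a$p, mean(a$sim <= a$obs))
  # the focal keeps its category, so no permutation can doom it
  expect_equal(length(a$sim), 100)
  expect_true(all(is.finite(a$sim)))

  c2 <- monteCarloTest(tr, st, spec, "sp0003", nPerm = 50,
                       scheme = "lapointe_garland", k = 1, seed = 7)
  d2 <- monteCarloTest(tr, st, spec, "sp0003", nPerm = 50,
                       scheme = "lapointe_garland", k = 1, seed = 7)
  expect_identical(c2$sim, d2$sim)

  stCR <- st
  stCR$category[stCR$species == "sp0003"] <- "CR"
  expect_error(monteCarloTest(tr, stCR, spec, "sp0003", nPerm = 10),
               "focal-extinct")
  expect_error(monteCarloTest(tr, st, spec, "sp0003", nPerm = 0), "nPerm")
})

test_that("the fast rank engine agrees with explicit pruning", {
  for (i in 1:30) {
    tr <- simulateTree(sample(10:40, 1), seed = 1300 + i)
    eng <- phyloiso:::.edEngine(tr)
    surv <- sample(tr$tip.label, sample(3:ape::Ntip(tr), 1))
    ref <- originalityTable(pruneTo(tr, surv))
    got <- eng$rankFor(surv)
    expect_equal(got[ref$species], stats::setNames(ref$rank, ref$species))
  }
  # and through the public test runner: Obs equals scenarioRank
  tr <- simulateTree(30, seed = 1400)
  st <- simulateStatuses(tr, w = 0.5, focal = "sp0010", seed = 1401)
  spec <- scenarioSpec("EN")
  res <- monteCarloTest(tr, st, spec, "sp0010", nPerm = 5, seed = 1)
  expect_equal(res$obs, as.numeric(scenarioRank(tr, st, spec, "sp0010")))
})
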