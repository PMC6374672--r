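#' Uniform permutation of risk statuses among non-focal species
#'
#' Randomly reassigns the observed categories among all species except the
#' focal one; the focal species keeps its category and the category multiset
#' is preserved.
#'
#' @param statuses a status table.
#' @param focal focal species id (must be present).
#' @return a permuted status table.
#' @export
permuteUniform <- function(statuses, focal) {
  .assertStatusTable(statuses)
  idx <- which(statuses$species != focal)
  if (length(idx) == nrow(statuses))
    stop("focal species '", focal, "' not in the status table")
  statuses$category[idx] <- statuses$category[idx[sample.int(length(idx))]]
  statuses
}

#' Phylogenetic exchange weights for constrained permutations
#'
#' Weight for species `i` and `j` to exchange risk status:
#' `w_ij = (1 - d_ij / d_max)^(1/k)` with `d_max` the largest tip-to-tip
#' patristic distance and `w_ii = 1`. At `k = 1` exchanges are strongly
#' constrained by the phylogeny (the most distant pair has weight 0); as
#' `k -> Inf` all weights tend to 1 and the permutation becomes uniform.
#'
#' @param d a patristic distance matrix (see [patristicMatrix()]).
#' @param k constraint parameter, `k >= 1` (use `Inf` for the uniform limit).
#' @return a symmetric weight matrix in `[0, 1]` with unit diagonal.
#' @export
lgWeights <- function(d, k = 1) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), k >= 1)
  dmax <- max(d[row(d) != col(d)])
  if (dmax <= 0) stop("all pairwise distances are zero; weights undefined")
  w <- (1 - d / dmax)^(1 / k)
  diag(w) <- 1
  w
}

#' Phylogenetically constrained permutation of risk statuses
#'
#' Sequential constrained reassignment: non-focal species are visited in a
#' freshly shuffled order; each visited species receives one not-yet-assigned
#' status, drawn among the remaining donor species with probability
#' proportional to the exchange weight [lgWeights()] between recipient and
#' donor. The category multiset is preserved and the focal species is never
#' touched. If every remaining donor has weight zero for some recipient, the
#' draw falls back to uniform among the remaining donors (counted in
#' attribute `n_fallback`).
#'
#' @param statuses a status table; all species must be tips of `tree`.
#' @param tree a `phylo` object.
#' @param k constraint parameter (`k >= 1`; `k = 1` strongest constraint).
#' @param focal focal species id.
#' @param weights optional precomputed weight matrix with species dimnames
#'   (saves recomputation across many permutations).
#' @return a permuted status table with attribute `n_fallback`.
#' @export
permuteLG <- function(statuses, tree, k = 1, focal, weights = NULL) {
  .assertStatusTable(statuses)
  if (!focal %in% statuses$species)
    stop("focal species '", focal, "' not in the status table")
  if (is.null(weights)) {
    miss <- setdiff(statuses$species, tree$tip.label)
    if (length(miss))
      stop("species not in tree: ", paste(utils::head(miss, 5), collapse = ", "))
    weights <- lgWeights(patristicMatrix(tree), k)
  }
  W <- weights[statuses$species, statuses$species, drop = FALSE]
  nonFocal <- which(statuses$species != focal)
  visit <- sample(nonFocal)
  remaining <- nonFocal
  newCat <- statuses$category
  nFallback <- 0L
  for (i in visit) {
    wr <- W[i, remaining]
    tot <- sum(wr)
    pick <- if (tot <= 0) {
      nFallback <- nFallback + 1L
      sample.int(length(remaining), 1L)
    } else {
      sample.int(length(remaining), 1L, prob = wr)
    }
    j <- remaining[pick]
    newCat[i] <- statuses$category[j]
    remaining <- remaining[-pick]
  }
  statuses$category <- newCat
  attr(statuses, "n_fallback") <- nFallback
  statuses
}

## Monte Carlo p: proportion of simulated ranks lower than or equal to the
## observed rank (plug-in form; optional (s+1)/(n+1) correction).
.mc_p <- function(sim, obs, corrected = FALSE) {
  s <- sum(sim <= obs)
  if (corrected) (s + 1) / (length(sim) + 1) else s / length(sim)
}

#' Significance codes for Monte Carlo p-values
#'
#' `"*"` for `0.01 < p <= 0.05`, `"**"` for `0.005 < p <= 0.01`, `"***"` for
#' `p <= 0.005`, empty otherwise.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of codes.
#' @export
significanceCode <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p <= 0.005, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

## Fast scenario-rank engine for repeated permutations on one fixed tree.
##
## The fair-proportion score on the survivor-induced subtree equals, for each
## surviving tip, the sum over original edges b on its root path of
## L_b / n_b(S), where n_b(S) counts surviving tips below b, restricted to
## edges with 1 <= n_b(S) < |S| (edges above the survivors' MRCA form the
## pruned tree's root stem, which is dropped). With a dense edge x tip
## incidence matrix this is two matrix-vector products per permutation.
## Large trees fall back to explicit pruning.
.edEngine <- function(tree, recomputeED = TRUE, maxDense = 2000L) {
  .assertPhylo(tree)
  n <- ape::Ntip(tree)
  labels <- tree$tip.label
  if (!recomputeED) {
    edFull <- computeED(tree)
    ed <- setNames(edFull$ed_my, edFull$species)
    rankFor <- function(surv) {
      e <- ed[surv]
      setNames(rank(-round(e / 1e-9), ties.method = "average"), surv)
    }
  } else if (n <= maxDense) {
    E <- nrow(tree$edge)
    L <- tree$edge.length
    ## tips below every node, by postorder accumulation
    tipsBelow <- vector("list", n + tree$Nnode)
    for (i in seq_len(n)) tipsBelow[[i]] <- i
    po <- stats::reorder(tree, "postorder")
    for (e in seq_len(nrow(po$edge))) {
      p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
      tipsBelow[[p]] <- c(tipsBelow[[p]], tipsBelow[[ch]])
    }
    M <- matrix(0, E, n)
    for (e in seq_len(E)) M[e, tipsBelow[[tree$edge[e, 2L]]]] <- 1
    rankFor <- function(surv) {
      s <- as.numeric(labels %in% surv)
      kS <- sum(s)
      nS <- drop(M %*% s)
      w <- numeric(E)
      keep <- nS > 0 & nS < kS
      w[keep] <- L[keep] / nS[keep]
      ed <- drop(crossprod(M, w))
      idx <- which(s > 0)
      ## same tie grid as rankByED, so both routes rank identically
      setNames(rank(-round(ed[idx] / 1e-9), ties.method = "average"),
               labels[idx])
    }
  } else {
    rankFor <- function(surv) {
      tab <- originalityTable(pruneTo(tree, surv))
      setNames(tab$rank, tab$species)
    }
  }
  focalRankFor <- function(surv, focal) {
    surv <- intersect(surv, labels)
    if (length(surv) < 2L)
      stop("fewer than 2 surviving species present in the tree")
    if (!focal %in% surv) stop("focal-extinct: focal not among survivors")
    unname(rankFor(surv)[focal])
  }
  list(rankFor = rankFor, focalRankFor = focalRankFor, labels = labels)
}

#' Monte Carlo test of a focal species' scenario rank against a null
#'
#' Computes the observed originality rank of the focal species after the
#' scenario's extinctions (`Obs`), then repeats the scenario on status tables
#' permuted among non-focal species -- uniformly or under the phylogenetically
#' constrained scheme (see [permuteLG()]) -- to obtain a null sample of
#' simulated ranks (`Sim`). The p-value is the proportion of permutations
#' with `Sim <= Obs`: small p means the focal species gains more originality
#' from the observed extinction pattern than expected were risk statuses
#' random across the tips. Because the focal species keeps its category, it
#' survives every permutation.
#'
#' @param tree a `phylo` object.
#' @param statuses a status table; DD species are resolved by the scenario's
#'   DD policy (for `"imputed"`, pass pre-imputed statuses).
#' @param spec a [scenarioSpec()].
#' @param focal focal species id.
#' @param nPerm number of permutations (>= 1). Contexts with many replicate
#'   data sets typically lower this (e.g. 200--500).
#' @param scheme `"uniform"` or `"lapointe_garland"`.
#' @param k constraint parameter for the constrained scheme (default 1, the
#'   strongest phylogenetic constraint).
#' @param seed optional RNG seed; identical seeds give identical results.
#' @param recomputeED recompute ED on each pruned tree (default; see
#'   [scenarioRank()]).
#' @param correctedP use the `(s + 1) / (n + 1)` Monte Carlo correction
#'   instead of the plug-in proportion (default `FALSE`).
#' @return an object of class `phyloisoTest`: list with `obs`, `sim`,
#'   `meanSim`, `sdSim`, `p`, `code`, `nPerm`, `scheme`, `k`, `scenario`,
#'   `focal`, `nSurvivors`, `nSpecies`, `seed`.
#' @export
monteCarloTest <- function(tree, statuses, spec, focal, nPerm = 500,
                           scheme = c("uniform", "lapointe_garland"), k = 1,
                           seed = NULL, recomputeED = TRUE,
                           correctedP = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "scenarioSpec"))
  if (nPerm < 1) stop("'nPerm' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (spec$ddPolicy != "imputed")
    statuses <- applyDDPolicy(statuses, spec$ddPolicy)
  .assertStatusTable(statuses, ddFree = TRUE)

  placed <- statuses$species %in% tree$tip.label
  nUnplaced <- sum(!placed)
  statuses <- statuses[placed, , drop = FALSE]
  i <- match(focal, statuses$species)
  if (is.na(i)) stop("focal species '", focal, "' not placed in the tree")
  if (statuses$category[i] %in% spec$doomed)
    stop("focal-extinct: focal species is doomed under this scenario")

  eng <- .edEngine(tree, recomputeED)
  obs <- eng$focalRankFor(survivors(statuses, spec), focal)
  nSurv <- length(intersect(survivors(statuses, spec), tree$tip.label))

  W <- NULL
  if (scheme == "lapointe_garland") {
    d <- patristicMatrix(tree)[statuses$species, statuses$species, drop = FALSE]
    W <- lgWeights(d, k)
  }
  sim <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    ps <- if (scheme == "uniform") permuteUniform(statuses, focal)
          else permuteLG(statuses, tree, k, focal, weights = W)
    sim[b] <- eng$focalRankFor(survivors(ps, spec), focal)
  }
  p <- .mc_p(sim, obs, correctedP)
  structure(list(obs = obs, sim = sim, meanSim = mean(sim), sdSim = stats::sd(sim),
                 p = p, code = significanceCode(p), nPerm = nPerm,
                 scheme = scheme, k = if (scheme == "lapointe_garland") k else NA,
                 scenario = spec, focal = focal, nSurvivors = nSurv,
                 nSpecies = nrow(statuses), nUnplaced = nUnplaced,
                 seed = seed),
            class = "phyloisoTest")
}

#' @export
print.phyloisoTest <- function(x, ...) {
  cat("Monte Carlo originality-rank test for '", x$focal, "'\n", sep = "")
  cat("  scenario: {", paste(x$scenario$doomed, collapse = ","),
      "} doomed, DD ", x$scenario$ddPolicy, "; ", x$nSurvivors, "/",
      x$nSpecies, " species survive\n", sep = "")
  cat("  scheme: ", x$scheme,
      if (!is.na(x$k)) paste0(" (k = ", x$k, ")"), ", ",
      x$nPerm, " permutations\n", sep = "")
  cat(sprintf("  Obs. rank %.1f | mean Sim. %.2f (SD %.2f) | p = %.4g %s\n",
              x$obs, x$meanSim, x$sdSim, x$p, x$code))
  invisible(x)
}

#' One-line JSON record for a test result
#'
#' @param x a `phyloisoTest`.
#' @return a JSON string with fields obs, sim_mean, sim_sd, p, code, n_perm,
#'   scheme, seed.
#' @export
testResultJson <- function(x) {
  stopifnot(inherits(x, "phyloisoTest"))
  jsonlite::toJSON(list(obs = x$obs, sim_mean = x$meanSim, sim_sd = x$sdSim,
                        p = x$p, code = x$code, n_perm = x$nPerm,
                        scheme = x$scheme,
                        seed = if (is.null(x$seed)) NA else x$seed),
                   auto_unbox = TRUE, digits = NA, na = "null")
}
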