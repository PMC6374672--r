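#' Graft phylogenetically unplaced species onto an ultrametric tree
#'
#' Each unplaced species is attached at random inside the smallest
#' monophyletic clade (subtree) containing all currently placed members of
#' its family. The attachment edge is chosen with probability proportional to
#' its length, the attachment point is uniform along the chosen edge, and the
#' new pendant edge runs to the present (its length equals the age of the
#' attachment point), so the tree stays ultrametric. Species are inserted in
#' a randomized order, and tips grafted earlier are available as attachment
#' targets for later grafts of the same family. A family with a single placed
#' member degenerates to splitting that tip's pendant edge into a cherry.
#'
#' Families with no placed member fall back to the order-level MRCA subtree
#' when the clade map carries an `order` column, and to the whole tree
#' otherwise (with a warning).
#'
#' @param tree an ultrametric `phylo` object (tolerance `tol`).
#' @param placements `data.frame` with columns `species`, `family`: species
#'   lacking a tree position. Must not already be tips.
#' @param clades clade map for placed tips: `data.frame` with columns
#'   `species`, `family` and optionally `order`.
#' @param tol absolute ultrametricity tolerance in MY (default `1e-6`).
#' @return the enlarged `phylo` object, with attribute `graft_log`: one row
#'   per graft (`species`, `family`, `edge_tips` -- the tip set below the
#'   chosen edge at attachment time --, `position`, `pendant_length`,
#'   `fallback`).
#' @export
graftRandomTips <- function(tree, placements, clades, tol = 1e-6) {
  .assertPhylo(tree)
  if (nrow(placements) == 0L) {
    attr(tree, "graft_log") <- data.frame()
    return(tree)
  }
  if (!all(c("species", "family") %in% names(placements)))
    stop("'placements' needs columns species, family")
  if (!all(c("species", "family") %in% names(clades)))
    stop("'clades' needs columns species, family")
  already <- intersect(placements$species, tree$tip.label)
  if (length(already))
    stop("species already placed in the tree: ",
         paste(utils::head(already, 5), collapse = ", "))
  if (!isUltrametric(tree, tol))
    stop("tree is not ultrametric within tol = ", tol)

  fam <- setNames(as.character(clades$family), clades$species)
  ord <- if ("order" %in% names(clades))
    setNames(as.character(clades$order), clades$species) else NULL

  log <- vector("list", nrow(placements))
  insertion <- sample(nrow(placements))
  for (step in seq_along(insertion)) {
    rowi <- insertion[step]
    sp <- placements$species[rowi]
    f <- as.character(placements$family[rowi])
    fallback <- "none"
    members <- intersect(names(fam)[fam == f], tree$tip.label)
    if (!length(members) && !is.null(ord)) {
      ofam <- unique(ord[names(fam)[fam == f]])
      ofam <- ofam[!is.na(ofam)]
      if (length(ofam)) {
        members <- intersect(names(ord)[ord %in% ofam], tree$tip.label)
        if (length(members)) fallback <- "order"
      }
    }
    if (!length(members)) {
      members <- tree$tip.label
      fallback <- "root"
      warning("family '", f, "' has no placed member; grafting '", sp,
              "' anywhere below the root")
    }

    if (length(members) == 1L) {
      candChildren <- match(members, tree$tip.label)
    } else {
      node <- ape::getMRCA(tree, members)
      candChildren <- .descendantNodes(tree, node)
    }
    edgeIdx <- match(candChildren, tree$edge[, 2L])
    len <- tree$edge.length[edgeIdx]
    pick <- if (sum(len) <= 0) sample.int(length(edgeIdx), 1L)
            else sample.int(length(edgeIdx), 1L, prob = len)
    e <- edgeIdx[pick]
    child <- tree$edge[e, 2L]
    u <- stats::runif(1, 0, tree$edge.length[e])

    ages <- .nodeAges(tree)
    pendant <- ages[child] + u
    nTip <- ape::Ntip(tree)
    below <- if (child <= nTip) child
             else intersect(.descendantNodes(tree, child), seq_len(nTip))
    log[[step]] <- data.frame(
      species = sp, family = f,
      edge_tips = paste(sort(tree$tip.label[below]), collapse = "|"),
      position = u, pendant_length = pendant, fallback = fallback,
      stringsAsFactors = FALSE)

    tree <- phytools::bind.tip(tree, sp, edge.length = pendant,
                               where = child, position = u)
    ## bind.tip registers the species as placed for subsequent grafts
    fam[sp] <- f
    if (!is.null(ord)) {
      ofam <- unique(ord[names(fam)[fam == f & names(fam) != sp]])
      ord[sp] <- if (length(ofam)) ofam[1] else NA_character_
    }
  }
  if (!isUltrametric(tree, max(tol, 1e-6)))
    stop("internal error: grafting broke ultrametricity")
  attr(tree, "graft_log") <- do.call(rbind, log)
  tree
}

.modeOf <- function(x) {
  t <- table(x)
  names(t)[which.max(t)]
}

#' Impute data-deficient risk statuses from taxonomy and traits
#'
#' Iterative nonparametric imputation in the style of missForest: missing
#' predictor cells are initialized by column median (numeric) or mode
#' (categorical) and DD statuses by the global status mode; then each
#' incomplete column in turn is refit with a random forest on the currently
#' completed data and its originally missing cells re-predicted. Iteration
#' stops when the column-wise change between successive imputations first
#' increases (the previous iterate is kept) or after `maxIter` rounds.
#'
#' Predictors are taxonomy (`order`, `family`), log body mass and log
#' geographic range size; any of them may carry missing values and is then
#' itself imputed during the loop. By default the final category for each DD
#' species is drawn from the forest's class vote proportions rather than the
#' majority vote, so repeated imputations express prediction uncertainty
#' (set `draw = "mode"` for deterministic majority-vote imputation).
#'
#' @param traits `data.frame` with columns `species`, `order`, `family`,
#'   `body_mass_g`, `range_km2` (mass/range may be `NA`).
#' @param statuses a status table; DD entries are the ones to impute.
#' @param maxIter maximum refit rounds (default 10).
#' @param ntree trees per forest (default 100).
#' @param draw `"sample"` (default) or `"mode"`: how the final DD category is
#'   taken from the forest vote distribution.
#' @param seed optional RNG seed.
#' @return a DD-free status table (non-DD rows untouched) with attribute
#'   `iterations`.
#' @export
imputeStatuses <- function(traits, statuses, maxIter = 10L, ntree = 100L,
                           draw = c("sample", "mode"), seed = NULL) {
  draw <- match.arg(draw)
  .assertStatusTable(statuses)
  if (!is.null(seed)) set.seed(seed)
  ddIdx <- which(statuses$category == "DD")
  if (!length(ddIdx)) return(statuses)
  if (length(ddIdx) == nrow(statuses))
    stop("all species are data deficient; nothing to learn from")
  if (!all(c("species") %in% names(traits)))
    stop("'traits' needs a species column")

  j <- match(statuses$species, traits$species)
  df <- data.frame(row.names = statuses$species)
  addFactor <- function(df, col) {
    if (col %in% names(traits)) {
      v <- factor(as.character(traits[[col]][j]))
      if (nlevels(v) > 53L) {
        warning("dropping predictor '", col, "': ", nlevels(v),
                " levels exceed the forest limit")
      } else if (nlevels(v) >= 2L) df[[col]] <- v
    }
    df
  }
  df <- addFactor(df, "order")
  df <- addFactor(df, "family")
  if ("body_mass_g" %in% names(traits)) df$log_mass <- log(traits$body_mass_g[j])
  if ("range_km2" %in% names(traits)) df$log_range <- log(traits$range_km2[j])
  df <- df[, colSums(!is.na(df)) > 0, drop = FALSE]
  if (!ncol(df)) stop("no usable predictors available")
  ## constant predictors carry no information (and stall the forest fit)
  varies <- vapply(df, function(col) {
    v <- col[!is.na(col)]
    length(unique(v)) >= 2L
  }, logical(1))
  if (!any(varies)) {
    ## no-information contract: draw DD categories from the observed
    ## status frequencies
    warning("all predictors are constant; imputing from the observed ",
            "category frequencies")
    obsCat <- statuses$category[-ddIdx]
    out <- statuses
    out$category[ddIdx] <- sample(obsCat, length(ddIdx), replace = TRUE)
    attr(out, "iterations") <- 0L
    return(out)
  }
  df <- df[, varies, drop = FALSE]
  df$status <- factor(ifelse(statuses$category == "DD", NA_character_,
                             statuses$category), levels = IUCN_CATEGORIES)

  missIdx <- lapply(df, function(col) which(is.na(col)))
  incomplete <- names(df)[vapply(missIdx, length, 0L) > 0L]
  incomplete <- incomplete[order(vapply(missIdx[incomplete], length, 0L))]

  ## initialize
  ximp <- df
  for (cn in names(ximp)) {
    mi <- missIdx[[cn]]
    if (!length(mi)) next
    if (is.numeric(ximp[[cn]])) {
      ximp[[cn]][mi] <- stats::median(ximp[[cn]][-mi])
    } else {
      ximp[[cn]][mi] <- .modeOf(df[[cn]][-mi])
    }
  }

  isNum <- vapply(ximp, is.numeric, logical(1))
  diffNum <- function(new, old) {
    cols <- intersect(incomplete, names(ximp)[isNum])
    if (!length(cols)) return(NULL)
    num <- den <- 0
    for (cn in cols) {
      mi <- missIdx[[cn]]
      num <- num + sum((new[[cn]][mi] - old[[cn]][mi])^2)
      den <- den + sum(new[[cn]][mi]^2)
    }
    if (den > 0) num / den else 0
  }
  diffCat <- function(new, old) {
    cols <- intersect(incomplete, names(ximp)[!isNum])
    if (!length(cols)) return(NULL)
    chg <- tot <- 0
    for (cn in cols) {
      mi <- missIdx[[cn]]
      chg <- chg + sum(as.character(new[[cn]][mi]) != as.character(old[[cn]][mi]))
      tot <- tot + length(mi)
    }
    chg / tot
  }

  prevNum <- prevCat <- Inf
  best <- ximp
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    old <- ximp
    for (cn in incomplete) {
      mi <- missIdx[[cn]]
      obs <- setdiff(seq_len(nrow(ximp)), mi)
      x <- ximp[, setdiff(names(ximp), cn), drop = FALSE]
      y <- df[[cn]][obs]
      if (!is.numeric(y)) y <- droplevels(factor(y))
      rf <- randomForest::randomForest(x = x[obs, , drop = FALSE], y = y,
                                       ntree = ntree)
      pred <- stats::predict(rf, x[mi, , drop = FALSE])
      if (!is.numeric(df[[cn]]))
        pred <- factor(as.character(pred), levels = levels(df[[cn]]))
      ximp[[cn]][mi] <- pred
    }
    dN <- diffNum(ximp, old)
    dC <- diffCat(ximp, old)
    worseNum <- is.null(dN) || dN >= prevNum
    worseCat <- is.null(dC) || dC >= prevCat
    if (iter > 1L && worseNum && worseCat) {
      ximp <- old
      break
    }
    best <- ximp
    if (!is.null(dN)) prevNum <- dN
    if (!is.null(dC)) prevCat <- dC
    if ((is.null(dN) || dN == 0) && (is.null(dC) || dC == 0)) break
  }

  out <- statuses
  if (draw == "sample") {
    ## refit on the converged iterate so the vote distribution matches it
    x <- best[, setdiff(names(best), "status"), drop = FALSE]
    obs <- setdiff(seq_len(nrow(best)), ddIdx)
    statusForest <- randomForest::randomForest(
      x = x[obs, , drop = FALSE], y = droplevels(df$status[obs]), ntree = ntree)
    pr <- stats::predict(statusForest, x[ddIdx, , drop = FALSE], type = "prob")
    cats <- colnames(pr)
    out$category[ddIdx] <- vapply(seq_along(ddIdx), function(r) {
      p <- pr[r, ]
      if (sum(p) <= 0) .modeOf(statuses$category[-ddIdx])
      else sample(cats, 1L, prob = p)
    }, character(1))
  } else {
    out$category[ddIdx] <- as.character(best$status[ddIdx])
  }
  attr(out, "iterations") <- iter
  out
}

#' Build an ensemble of completed (tree, status) data sets
#'
#' Each replicate independently grafts the unplaced species onto each core
#' tree ([graftRandomTips()]) and, when DD species and traits are available,
#' independently imputes their statuses ([imputeStatuses()]). Replicate-level
#' seeds are derived deterministically from the master seed, so the ensemble
#' is reproducible and order-independent.
#'
#' @param trees a `phylo`, a list of `phylo`, or a `multiPhylo`: the core
#'   trees.
#' @param statuses a status table (may contain DD).
#' @param traits trait table for imputation (may be `NULL` when no DD).
#' @param placements placement table for grafting (may be `NULL` or empty).
#' @param nRep replicates per core tree (>= 1).
#' @param seed master seed.
#' @param clades clade map for grafting; defaults to the taxonomy columns of
#'   `traits`.
#' @param materialize when `FALSE`, return only the manifest (replicate id,
#'   tree index, derived seed) without computing the data sets.
#' @return a list of data sets (`tree`, `statuses`, `seed`, `treeIndex`,
#'   `rep`) with attribute `manifest`; or the manifest `data.frame` alone.
#' @export
buildReplicates <- function(trees, statuses, traits = NULL, placements = NULL,
                            nRep = 1L, seed = 1L, clades = NULL,
                            materialize = TRUE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(nRep >= 1L, length(trees) >= 1L)
  .assertStatusTable(statuses)
  if (is.null(clades) && !is.null(traits) &&
      all(c("species", "family") %in% names(traits)))
    clades <- traits[, intersect(c("species", "order", "family"), names(traits))]

  m <- nRep * length(trees)
  set.seed(seed)
  seeds <- sample.int(2147483646L, m)
  manifest <- data.frame(
    replicate = seq_len(m),
    tree = rep(seq_along(trees), each = nRep),
    rep = rep(seq_len(nRep), times = length(trees)),
    seed = seeds)
  if (!materialize) return(manifest)

  hasDD <- any(statuses$category == "DD")
  datasets <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(manifest$seed[i])
    tr <- trees[[manifest$tree[i]]]
    if (!is.null(placements) && nrow(placements)) {
      if (is.null(clades)) stop("grafting requires a clade map")
      tr <- graftRandomTips(tr, placements, clades)
    }
    st <- statuses
    if (hasDD && !is.null(traits))
      st <- imputeStatuses(traits, statuses)
    datasets[[i]] <- list(tree = tr, statuses = st, seed = manifest$seed[i],
                          treeIndex = manifest$tree[i], rep = manifest$rep[i])
  }
  attr(datasets, "manifest") <- manifest
  datasets
}

#' Median evolutionary distinctiveness across an ensemble
#'
#' The per-species median ED over the completed data sets, useful as a
#' missing-data-robust originality covariate.
#'
#' @param datasets a materialized ensemble from [buildReplicates()].
#' @return `data.frame` with columns `species`, `median_ed`.
#' @export
ensembleMedianED <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  eds <- lapply(datasets, function(d) {
    t <- computeED(d$tree)
    setNames(t$ed_my, t$species)
  })
  spp <- sort(unique(unlist(lapply(eds, names))))
  med <- vapply(spp, function(s) {
    stats::median(unlist(lapply(eds, function(e) e[s])), na.rm = TRUE)
  }, numeric(1))
  data.frame(species = spp, median_ed = unname(med), stringsAsFactors = FALSE)
}
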