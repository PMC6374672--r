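#' @importFrom stats cophenetic rnorm runif sd setNames quantile ks.test
#' @importFrom utils read.csv write.csv
NULL

## Category constants used throughout: the five ordinal IUCN risk categories
## (least concern -> critically endangered) plus the data-deficient flag.

#' Ordinal IUCN risk categories, least to most threatened
#' @export
IUCN_CATEGORIES <- c("LC", "NT", "VU", "EN", "CR")

#' All accepted category codes (ordinal categories plus data deficient)
#' @export
IUCN_CODES <- c(IUCN_CATEGORIES, "DD")

.assertPhylo <- function(tree, minTips = 2L) {
  if (!inherits(tree, "phylo"))
    stop("'tree' must be a \"phylo\" object", call. = FALSE)
  n <- ape::Ntip(tree)
  if (n < minTips)
    stop("tree has ", n, " tip(s); at least ", minTips, " required", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  lab <- tree$tip.label
  if (any(!nzchar(lab)) || anyNA(lab))
    stop("empty or missing tip labels", call. = FALSE)
  if (anyDuplicated(lab))
    stop("duplicate tip labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "), call. = FALSE)
  invisible(tree)
}

#' Read a rooted, branch-length-bearing tree from Newick
#'
#' Reads one tree from a Newick file or string and validates it for downstream
#' originality analysis: unique non-empty tip labels, branch lengths on every
#' edge, no negative lengths. Any root stem (length hanging above the root) is
#' dropped: a stem subtends every tip, adds the same constant to every
#' evolutionary distinctiveness score, and can never change an originality
#' rank.
#'
#' @param file path to a Newick file, or a literal Newick string (anything
#'   containing "(" is treated as text).
#' @param index which tree to take from a multi-tree file (default first).
#' @param underscoresToSpaces convert underscores in tip labels to spaces so
#'   labels join exactly against species names in CSV tables (default `TRUE`).
#' @param allowSingleTip accept a degenerate single-tip tree instead of
#'   raising an error (default `FALSE`).
#' @return a validated `phylo` object with no `root.edge`.
#' @export
readNewick <- function(file, index = 1L, underscoresToSpaces = TRUE,
                       allowSingleTip = FALSE) {
  if (length(file) != 1L || !is.character(file))
    stop("'file' must be a single path or Newick string")
  tr <- if (grepl("(", file, fixed = TRUE)) {
    ape::read.tree(text = file)
  } else {
    ape::read.tree(file)
  }
  if (is.null(tr)) stop("malformed Newick input")
  if (inherits(tr, "multiPhylo")) {
    if (index < 1L || index > length(tr))
      stop("tree index ", index, " out of range (file holds ", length(tr), ")")
    tr <- tr[[index]]
  }
  if (underscoresToSpaces)
    tr$tip.label <- gsub("_", " ", tr$tip.label, fixed = TRUE)
  tr$root.edge <- NULL
  .assertPhylo(tr, minTips = if (allowSingleTip) 1L else 2L)
  tr
}

#' Write a tree to Newick
#'
#' Spaces in tip labels are converted back to underscores, the inverse of
#' [readNewick()]'s normalization, so that write/read round-trips are exact.
#'
#' @param tree a `phylo` object.
#' @param file output path; if `NULL` the Newick string is returned.
#' @return the path (invisibly) or the Newick string.
#' @export
writeNewick <- function(tree, file = NULL) {
  tree$tip.label <- gsub(" ", "_", tree$tip.label, fixed = TRUE)
  txt <- ape::write.tree(tree, digits = 17)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' Prune a tree to a set of tips
#'
#' Returns the induced subtree on `keep`: unifurcations are suppressed with
#' their lengths summed, and any stem left above the new root is removed, so
#' pairwise patristic distances among kept tips are exactly preserved.
#'
#' The removed stem's total length (the path from the original root down to
#' the kept tips' MRCA) is recorded as attribute `stem_length`; it is the
#' constant `stem_length / |keep|` share of ED that every kept tip gives up
#' when the stem is dropped (ranks are unaffected).
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo` object with attribute `stem_length`.
#' @export
pruneTo <- function(tree, keep) {
  .assertPhylo(tree)
  keep <- unique(as.character(keep))
  bad <- setdiff(keep, tree$tip.label)
  if (length(bad))
    stop("unknown tip label(s): ", paste(utils::head(bad, 5), collapse = ", "))
  if (length(keep) < 2L)
    stop("need at least 2 tips to keep, got ", length(keep))
  stem <- .nodeDepths(tree)[mrcaNode(tree, keep)]
  out <- ape::keep.tip(tree, keep)
  out$root.edge <- NULL
  attr(out, "stem_length") <- stem
  out
}

#' Tip-to-tip patristic distance matrix
#'
#' Sum of branch lengths along the tree path between every pair of tips, in
#' the tree's length units (MY for a timetree). On an ultrametric tree
#' `d(i, j) = 2 * age(MRCA(i, j))`.
#'
#' @param tree a `phylo` object.
#' @return a symmetric numeric matrix with tip labels as dimnames.
#' @export
patristicMatrix <- function(tree) {
  .assertPhylo(tree)
  as.matrix(stats::cophenetic(tree))
}

#' Most recent common ancestor of a tip set
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels (non-empty). For a single tip
#'   the MRCA is that tip itself.
#' @return the node number (tip number for a single tip).
#' @export
mrcaNode <- function(tree, tips) {
  .assertPhylo(tree)
  tips <- unique(as.character(tips))
  if (!length(tips)) stop("'tips' must be non-empty")
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip label(s): ", paste(tips[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, tips)
}

## Root-to-node path lengths for every node (tips first, then internals).
.nodeDepths <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  cw <- stats::reorder(tree, "cladewise")
  depth <- numeric(nn)
  for (e in seq_len(nrow(cw$edge)))
    depth[cw$edge[e, 2L]] <- depth[cw$edge[e, 1L]] + cw$edge.length[e]
  depth
}

#' Height of a tree (maximum root-to-tip path length)
#' @param tree a `phylo` object.
#' @return numeric height in branch-length units.
#' @export
treeHeight <- function(tree) {
  .assertPhylo(tree, minTips = 1L)
  max(.nodeDepths(tree)[seq_len(ape::Ntip(tree))])
}

## Node ages (time before present); meaningful for ultrametric trees.
.nodeAges <- function(tree) {
  d <- .nodeDepths(tree)
  treeHeight(tree) - d
}

#' Test whether a tree is ultrametric within an absolute tolerance
#'
#' All root-to-tip path lengths must agree within `tol` (same units as the
#' branch lengths, i.e. MY for a timetree). This is an absolute criterion,
#' appropriate for grafting on dated trees where drift is bounded in MY.
#'
#' @param tree a `phylo` object.
#' @param tol non-negative absolute tolerance (default `1e-6`).
#' @return logical.
#' @export
isUltrametric <- function(tree, tol = 1e-6) {
  .assertPhylo(tree, minTips = 1L)
  stopifnot(tol >= 0)
  d <- .nodeDepths(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol
}

#' Total branch length of a tree
#' @param tree a `phylo` object.
#' @return numeric sum of all edge lengths (excluding any root stem).
#' @export
totalBranchLength <- function(tree) {
  .assertPhylo(tree, minTips = 1L)
  sum(tree$edge.length)
}

## All descendant nodes (tips and internals) strictly below `node`.
.descendantNodes <- function(tree, node) {
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer(0)
  stack <- kids[[as.character(node)]]
  while (length(stack)) {
    out <- c(out, stack)
    nxt <- unlist(kids[as.character(stack)], use.names = FALSE)
    stack <- nxt
  }
  out
}

## Number of tips descending from the child node of every edge, plus an
## edge x tip incidence structure used by the fair-proportion machinery.
.edgeTipStructure <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  po <- stats::reorder(tree, "postorder")
  ntips <- numeric(nn)
  ntips[seq_len(n)] <- 1
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    ntips[p] <- ntips[p] + ntips[ch]
  }
  list(postorder = po, ntipsBelow = ntips)
}
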