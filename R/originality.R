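#' Evolutionary distinctiveness (fair proportion) scores
#'
#' Computes, for every tip, the evolutionary distinctiveness index ED: each
#' edge's length is divided equally among the tips descending from it, and a
#' tip's score is the sum of its shares along the root-to-tip path,
#' `ED_i = sum_b L_b / n_b` over edges `b` on the path, where `n_b` is the
#' number of tips below `b`. Scores are in branch-length units (MY for a
#' timetree) and sum exactly to the tree's total branch length. Any root stem
#' is excluded (see [readNewick()]); polytomies are handled natively.
#'
#' Scores are accumulated in a fixed root-ward depth-first edge order so that
#' structurally tied tips (e.g. the two tips of a cherry) receive bit-identical
#' scores and tie-averaging in [rankByED()] is reproducible. Near-ties arising
#' from distinct branch-length sums are not merged.
#'
#' @param tree a `phylo` object with at least 2 tips.
#' @return an originality table: `data.frame` with columns `species` and
#'   `ed_my`, one row per tip, plus attribute `total_length`.
#' @seealso [rankByED()], [focalRank()], [originalityTable()]
#' @export
computeED <- function(tree) {
  .assertPhylo(tree, minTips = 2L)
  n <- ape::Ntip(tree)
  st <- .edgeTipStructure(tree)
  cw <- stats::reorder(tree, "cladewise")
  acc <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1L]; ch <- cw$edge[e, 2L]
    acc[ch] <- acc[p] + cw$edge.length[e] / st$ntipsBelow[ch]
  }
  out <- data.frame(species = tree$tip.label, ed_my = acc[seq_len(n)],
                    stringsAsFactors = FALSE)
  attr(out, "total_length") <- sum(tree$edge.length)
  out
}

#' Originality ranks from ED scores
#'
#' Orders species from most to least original: rank 1 is the highest ED score.
#' Tied scores receive the average of the ranks they span. Ties are detected
#' on a fixed grid of `tieTolerance` MY (default 1 fm of evolutionary time,
#' `1e-9` MY): scores whose difference is only floating-point noise from
#' summing the same branch shares along different edge orders rank as tied,
#' while any real difference in branch lengths separates them. This makes
#' ranks identical across algebraically equivalent computation orders.
#'
#' @param table an originality table from [computeED()].
#' @param tieTolerance grid width for tie detection, in MY.
#' @return the table with a `rank` column added; ranks are a permutation of
#'   `1..n` with tied groups replaced by their mean.
#' @export
rankByED <- function(table, tieTolerance = 1e-9) {
  if (!is.data.frame(table) || !all(c("species", "ed_my") %in% names(table)))
    stop("'table' must be an originality table with columns species, ed_my")
  table$rank <- rank(-round(table$ed_my / tieTolerance), ties.method = "average")
  table
}

#' Originality rank of a focal species
#'
#' @param table a ranked originality table (see [rankByED()]).
#' @param focal species id. An absence error signals that the focal species
#'   was pruned away (e.g. went extinct under a scenario).
#' @return the focal species' rank (real; 1 = most original).
#' @export
focalRank <- function(table, focal) {
  if (is.null(table$rank)) table <- rankByED(table)
  i <- match(focal, table$species)
  if (is.na(i))
    stop("focal species '", focal, "' not present in the originality table")
  table$rank[i]
}

#' ED scores and originality ranks in one call
#'
#' @param tree a `phylo` object.
#' @return a ranked originality table (columns `species`, `ed_my`, `rank`).
#' @export
originalityTable <- function(tree) {
  rankByED(computeED(tree))
}

#' Write an originality table to CSV
#'
#' Columns `species`, `ed_my`, `rank`, sorted by rank (most original first).
#'
#' @param table a ranked originality table.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeOriginalityCsv <- function(table, file) {
  if (is.null(table$rank)) table <- rankByED(table)
  table <- table[order(table$rank), c("species", "ed_my", "rank")]
  utils::write.csv(table, file, row.names = FALSE)
  invisible(file)
}
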