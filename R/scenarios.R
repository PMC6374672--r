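## The four nested extinction scenarios: all species at or above a threat
## threshold are driven extinct. LC extinction is never simulated.
.SCENARIO_SETS <- list(
  CR = "CR",
  EN = c("EN", "CR"),
  VU = c("VU", "EN", "CR"),
  NT = c("NT", "VU", "EN", "CR")
)

#' Construct an extinction-scenario specification
#'
#' A scenario is a nested doomed-category set -- one of `{CR}`, `{EN,CR}`,
#' `{VU,EN,CR}`, `{NT,VU,EN,CR}` -- plus a policy for data-deficient species.
#' The DD extremes treat every DD species as least concern (`"as_LC"`) or as
#' critically endangered (`"as_CR"`); `"imputed"` expects statuses completed
#' by [imputeStatuses()].
#'
#' @param doomed either a threshold level (`"CR"`, `"EN"`, `"VU"`, `"NT"`,
#'   meaning that level and everything more threatened goes extinct) or the
#'   explicit category vector of one of the four nested sets.
#' @param ddPolicy one of `"as_LC"`, `"as_CR"`, `"imputed"`.
#' @return an object of class `scenarioSpec`.
#' @export
scenarioSpec <- function(doomed = "CR", ddPolicy = c("as_LC", "as_CR", "imputed")) {
  ddPolicy <- match.arg(ddPolicy)
  if (length(doomed) == 1L && doomed %in% names(.SCENARIO_SETS)) {
    doomed <- .SCENARIO_SETS[[doomed]]
  }
  doomed <- sort(unique(as.character(doomed)))
  ok <- vapply(.SCENARIO_SETS, function(s) identical(sort(s), doomed), logical(1))
  if (!any(ok))
    stop("'doomed' must be one of the nested sets {CR}, {EN,CR}, {VU,EN,CR}, ",
         "{NT,VU,EN,CR}; LC species are never doomed")
  structure(list(doomed = .SCENARIO_SETS[[which(ok)]], ddPolicy = ddPolicy),
            class = "scenarioSpec")
}

#' @export
print.scenarioSpec <- function(x, ...) {
  cat("Extinction scenario: {", paste(x$doomed, collapse = ", "),
      "} doomed; DD policy:", x$ddPolicy, "\n")
  invisible(x)
}

.assertStatusTable <- function(statuses, ddFree = FALSE) {
  if (!is.data.frame(statuses) ||
      !all(c("species", "category") %in% names(statuses)))
    stop("status table must have columns 'species' and 'category'")
  if (anyDuplicated(statuses$species))
    stop("duplicate species in status table")
  bad <- setdiff(unique(statuses$category), IUCN_CODES)
  if (length(bad))
    stop("invalid IUCN categories (extinct species must be excluded upstream): ",
         paste(bad, collapse = ", "))
  if (ddFree && any(statuses$category == "DD"))
    stop("status table still contains DD species; apply a DD policy first")
  invisible(statuses)
}

#' Read a species status table from CSV
#'
#' Expects columns `species, category` with uppercase two-letter IUCN codes.
#' Extinct (EX) and extinct-in-the-wild (EW) species are rejected at load:
#' the analysis concerns extant species only.
#'
#' @param file CSV path.
#' @return a `data.frame` with columns `species`, `category`.
#' @export
readStatusCsv <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (any(x$category %in% c("EX", "EW")))
    stop("status table contains extinct (EX/EW) species; exclude them first")
  .assertStatusTable(x[, c("species", "category")])
}

#' Write a status table to CSV
#' @param statuses a status table.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeStatusCsv <- function(statuses, file) {
  .assertStatusTable(statuses)
  utils::write.csv(statuses[, c("species", "category")], file, row.names = FALSE)
  invisible(file)
}

#' Ordinal risk codes for IUCN categories
#'
#' LC=0, NT=1, VU=2, EN=3, CR=4; DD maps to `NA` (its risk is unknown, not
#' intermediate).
#'
#' @param categories character vector of category codes.
#' @return integer vector of ordinal codes.
#' @export
statusOrdinal <- function(categories) {
  m <- match(categories, IUCN_CATEGORIES) - 1L
  m
}

#' Resolve data-deficient species to a definite category
#'
#' Under the extreme policies every DD species becomes LC (`"as_LC"`) or CR
#' (`"as_CR"`). Under `"imputed"`, categories predicted by
#' [imputeStatuses()] are substituted. Non-DD entries are never modified.
#'
#' @param statuses a status table.
#' @param policy `"as_LC"`, `"as_CR"` or `"imputed"`.
#' @param imputed for `policy = "imputed"`: a DD-free status table covering
#'   the DD species (typically the output of [imputeStatuses()]).
#' @return a DD-free status table.
#' @export
applyDDPolicy <- function(statuses, policy = c("as_LC", "as_CR", "imputed"),
                          imputed = NULL) {
  policy <- match.arg(policy)
  .assertStatusTable(statuses)
  dd <- statuses$category == "DD"
  if (!any(dd)) return(statuses)
  if (policy == "as_LC") {
    statuses$category[dd] <- "LC"
  } else if (policy == "as_CR") {
    statuses$category[dd] <- "CR"
  } else {
    if (is.null(imputed))
      stop("policy 'imputed' requires an imputation source (see imputeStatuses)")
    .assertStatusTable(imputed, ddFree = TRUE)
    j <- match(statuses$species[dd], imputed$species)
    if (anyNA(j))
      stop("imputation source missing ", sum(is.na(j)), " DD species")
    statuses$category[dd] <- imputed$category[j]
  }
  statuses
}

#' Species surviving an extinction scenario
#'
#' @param statuses a DD-free status table (apply a DD policy first).
#' @param spec a [scenarioSpec()].
#' @return character vector of surviving species ids (category not in the
#'   doomed set).
#' @export
survivors <- function(statuses, spec) {
  .assertStatusTable(statuses, ddFree = TRUE)
  stopifnot(inherits(spec, "scenarioSpec"))
  statuses$species[!(statuses$category %in% spec$doomed)]
}

#' Focal species' originality rank after a simulated extinction
#'
#' Prunes the tree to the scenario's survivors, recomputes evolutionary
#' distinctiveness on the pruned tree, and returns the focal species' rank
#' among survivors. Recomputation (rather than re-ranking pre-extinction
#' scores) reflects the focal species' position in the tree of surviving
#' species; set `recomputeED = FALSE` for the rank-among-survivors
#' alternative as a sensitivity check.
#'
#' Species present in the status table but absent from the tree (e.g.
#' phylogenetically unplaced) are ignored; their count is attached as
#' attribute `n_unplaced` (graft them first with [graftRandomTips()] to
#' include them).
#'
#' @param tree a `phylo` object.
#' @param statuses a status table (DD resolved via the scenario's policy;
#'   `"imputed"` requires pre-imputed input).
#' @param spec a [scenarioSpec()].
#' @param focal focal species id; must survive the scenario.
#' @param recomputeED recompute ED on the pruned tree (default) or rank
#'   pre-extinction scores among survivors.
#' @return the focal rank (real), with attribute `n_survivors` and
#'   `n_unplaced`.
#' @export
scenarioRank <- function(tree, statuses, spec, focal, recomputeED = TRUE) {
  .assertPhylo(tree)
  stopifnot(inherits(spec, "scenarioSpec"))
  if (spec$ddPolicy != "imputed") {
    statuses <- applyDDPolicy(statuses, spec$ddPolicy)
  }
  .assertStatusTable(statuses, ddFree = TRUE)
  i <- match(focal, statuses$species)
  if (is.na(i)) stop("focal species '", focal, "' not in the status table")
  if (statuses$category[i] %in% spec$doomed)
    stop("focal-extinct: focal species '", focal, "' has category ",
         statuses$category[i], ", which is doomed under this scenario")
  if (!focal %in% tree$tip.label)
    stop("focal species '", focal, "' is not a tip of the tree")
  surv <- survivors(statuses, spec)
  nUnplaced <- sum(!statuses$species %in% tree$tip.label)
  keep <- intersect(surv, tree$tip.label)
  if (length(keep) < 2L)
    stop("fewer than 2 surviving species present in the tree")
  if (recomputeED) {
    tab <- originalityTable(pruneTo(tree, keep))
  } else {
    tab <- computeED(tree)
    tab <- rankByED(tab[tab$species %in% keep, ])
  }
  r <- focalRank(tab, focal)
  attr(r, "n_survivors") <- length(keep)
  attr(r, "n_unplaced") <- nUnplaced
  r
}

#' Per-clade summary of species counts, originality and threat composition
#'
#' For each clade (family or order), reports `N`, the number of species
#' mapped to the clade in the status table (including DD and phylogenetically
#' unplaced species); `NO`, the number of the clade's placed species whose
#' full-tree ED is strictly greater than the focal species' (ties never
#' count); `NO_star`, the same count recomputed on the scenario-pruned tree;
#' and the percentage of the clade's species in each IUCN category
#' (including DD), summing to 100 per clade.
#'
#' @param tree a `phylo` object containing the focal species.
#' @param statuses a status table (may include DD).
#' @param clades a clade map: `data.frame` with columns `species` and the
#'   requested `level` column (`family` and/or `order`). To group clades
#'   (e.g. paraphyletic families), pre-merge their labels in that column.
#' @param focal focal species id.
#' @param spec a [scenarioSpec()] for the `NO_star` column (default: the
#'   threatened set `{VU,EN,CR}` with DD treated as LC).
#' @param level which clade column to summarize by (default `"family"`).
#' @return a `data.frame` with one row per clade: `clade`, `N`, `NO`,
#'   `NO_star`, `pct_LC` .. `pct_DD`.
#' @export
cladeSummary <- function(tree, statuses, clades, focal,
                         spec = scenarioSpec("VU", "as_LC"),
                         level = c("family", "order")) {
  level <- match.arg(level)
  .assertPhylo(tree)
  .assertStatusTable(statuses)
  if (!all(c("species", level) %in% names(clades)))
    stop("clade map must have columns 'species' and '", level, "'")
  if (!focal %in% tree$tip.label)
    stop("focal species '", focal, "' is not a tip of the tree")

  cl <- setNames(as.character(clades[[level]]), clades$species)
  if (anyNA(cl) || any(!nzchar(cl))) stop("every species needs a clade label")

  edFull <- computeED(tree)
  edFocal <- edFull$ed_my[match(focal, edFull$species)]
  moreOriginal <- edFull$species[edFull$ed_my > edFocal]

  resolved <- applyDDPolicy(statuses, if (spec$ddPolicy == "imputed") "as_LC"
                            else spec$ddPolicy)
  surv <- intersect(survivors(resolved, spec), tree$tip.label)
  moreOriginalStar <- character(0)
  if (length(surv) >= 2L && focal %in% surv) {
    edStar <- computeED(pruneTo(tree, surv))
    efs <- edStar$ed_my[match(focal, edStar$species)]
    moreOriginalStar <- edStar$species[edStar$ed_my > efs]
  }

  allClades <- sort(unique(cl))
  rows <- lapply(allClades, function(cc) {
    spp <- names(cl)[cl == cc]
    inTab <- statuses[statuses$species %in% spp, , drop = FALSE]
    N <- nrow(inTab)
    if (N == 0L) warning("clade '", cc, "' has zero species in the status table")
    pct <- vapply(IUCN_CODES, function(cat)
      if (N) 100 * sum(inTab$category == cat) / N else 0, numeric(1))
    data.frame(clade = cc, N = N,
               NO = sum(spp %in% moreOriginal),
               NO_star = sum(spp %in% moreOriginalStar),
               t(setNames(pct, paste0("pct_", IUCN_CODES))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Display thickness for a clade's terminal branch
#'
#' Thickness used to draw a collapsed clade of `N` species:
#' `log(1 + N) / log(2) * u`, where `u` is the basic thickness at `N = 1`.
#'
#' @param N number of species in the clade (>= 0).
#' @param u basic thickness (> 0).
#' @return numeric thickness.
#' @export
branchThickness <- function(N, u = 1) {
  stopifnot(all(N >= 0), all(u > 0))
  log(1 + N) / log(2) * u
}
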