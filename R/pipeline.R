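#' Configuration for a full ensemble analysis
#'
#' Exactly one input mode: file paths (`treeFile`, `statusFile`, plus
#' optional `traitFile`, `placementFile`) or a [syntheticConfig()] via
#' `synthetic`. Scenarios are threat thresholds; each expands to its nested
#' doomed set.
#'
#' @param treeFile,statusFile,traitFile,placementFile input paths (file
#'   mode). `treeFile` may be a vector of paths (one core tree each).
#' @param synthetic a [syntheticConfig()] (synthetic mode).
#' @param focal focal species id (file mode; the synthetic fixture carries
#'   its own).
#' @param scenarios character vector of thresholds among `"CR"`, `"EN"`,
#'   `"VU"`, `"NT"` (non-empty).
#' @param ddPolicy DD policy applied in every scenario (`"as_LC"`,
#'   `"as_CR"`, `"imputed"`).
#' @param scheme permutation scheme (`"uniform"` or `"lapointe_garland"`).
#' @param k constraint parameter for the constrained scheme.
#' @param nPerm permutations per Monte Carlo test.
#' @param nRep completed-data replicates per core tree.
#' @param seed master seed; every downstream RNG stream derives from it.
#' @param outDir output directory (`NULL` = no files written).
#' @param alpha nominal test level (default 0.05).
#' @param pooling how replicate p-values are pooled in the summary:
#'   `"mean_p"` (mean of replicate p-values) or `"pooled_sims"` (pooled Sim
#'   sample against the mean Obs).
#' @return an object of class `runConfig`.
#' @export
runConfig <- function(treeFile = NULL, statusFile = NULL, traitFile = NULL,
                      placementFile = NULL, synthetic = NULL, focal = NULL,
                      scenarios = c("CR", "EN", "VU", "NT"),
                      ddPolicy = "as_LC",
                      scheme = c("uniform", "lapointe_garland"), k = 1,
                      nPerm = 500L, nRep = 1L, seed = 1L, outDir = NULL,
                      alpha = 0.05, pooling = c("mean_p", "pooled_sims")) {
  scheme <- match.arg(scheme)
  pooling <- match.arg(pooling)
  fileMode <- !is.null(treeFile)
  if (fileMode == !is.null(synthetic))
    stop("exactly one input mode: file paths or a synthetic config")
  if (fileMode && is.null(statusFile)) stop("file mode needs 'statusFile'")
  if (fileMode && is.null(focal)) stop("file mode needs 'focal'")
  if (!length(scenarios)) stop("scenario list must be non-empty")
  stopifnot(all(scenarios %in% names(.SCENARIO_SETS)))
  structure(list(treeFile = treeFile, statusFile = statusFile,
                 traitFile = traitFile, placementFile = placementFile,
                 synthetic = synthetic, focal = focal, scenarios = scenarios,
                 ddPolicy = ddPolicy, scheme = scheme, k = k,
                 nPerm = as.integer(nPerm), nRep = as.integer(nRep),
                 seed = as.integer(seed), outDir = outDir, alpha = alpha,
                 pooling = pooling),
            class = "runConfig")
}

.loadInputs <- function(config) {
  if (!is.null(config$synthetic)) {
    fx <- makeFixture(config$synthetic)
    list(trees = list(fx$tree), statuses = fx$statuses, traits = fx$traits,
         placements = fx$placements, clades = fx$clades, focal = fx$focal)
  } else {
    trees <- lapply(config$treeFile, readNewick)
    traits <- if (!is.null(config$traitFile))
      utils::read.csv(config$traitFile, stringsAsFactors = FALSE) else NULL
    placements <- if (!is.null(config$placementFile))
      utils::read.csv(config$placementFile, stringsAsFactors = FALSE) else NULL
    list(trees = trees, statuses = readStatusCsv(config$statusFile),
         traits = traits, placements = placements,
         clades = if (!is.null(traits))
           traits[, intersect(c("species", "order", "family"), names(traits))]
         else NULL,
         focal = config$focal)
  }
}

#' Run the full originality-isolation analysis over an ensemble
#'
#' Builds the replicate ensemble of completed data sets (grafting unplaced
#' species, imputing DD statuses when the policy is `"imputed"`), then runs
#' one Monte Carlo test per (data set, scenario). Every permutation computes
#' one simulated originality vector; the manifest therefore counts exactly
#' `n_datasets * n_scenarios * n_perm` simulated vectors. Outputs (when
#' `outDir` is set): `results.csv` with one summary row per scenario,
#' `results_detail.csv` with one row per (data set, scenario), and
#' `manifest.json`. The run is fully reproducible from the master seed; a
#' scenario under which the focal species is doomed is reported as failed
#' and the run continues.
#'
#' @param config a [runConfig()].
#' @return (invisibly) a list: `results` (list of `phyloisoTest`), `detail`
#'   (`data.frame`), `summary` (Table-shaped `data.frame`), `manifest`.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  inp <- .loadInputs(config)
  set.seed(config$seed)
  masterSeeds <- sample.int(2147483646L, 2L)

  needImpute <- config$ddPolicy == "imputed" &&
    any(inp$statuses$category == "DD")
  hasPlacements <- !is.null(inp$placements) && nrow(inp$placements) > 0
  datasets <- if (hasPlacements || needImpute) {
    buildReplicates(inp$trees, inp$statuses,
                    traits = if (needImpute) inp$traits else NULL,
                    placements = inp$placements, nRep = config$nRep,
                    seed = masterSeeds[1], clades = inp$clades)
  } else {
    lapply(seq_len(config$nRep * length(inp$trees)), function(i) {
      list(tree = inp$trees[[((i - 1L) %% length(inp$trees)) + 1L]],
           statuses = inp$statuses, seed = NA_integer_,
           treeIndex = ((i - 1L) %% length(inp$trees)) + 1L, rep = i)
    })
  }

  nData <- length(datasets)
  nScen <- length(config$scenarios)
  set.seed(masterSeeds[2])
  testSeeds <- matrix(sample.int(2147483646L, nData * nScen), nData, nScen)

  results <- vector("list", nData * nScen)
  detail <- vector("list", nData * nScen)
  idx <- 0L
  for (i in seq_len(nData)) {
    for (s in seq_len(nScen)) {
      idx <- idx + 1L
      spec <- scenarioSpec(config$scenarios[s], config$ddPolicy)
      st <- datasets[[i]]$statuses
      if (config$ddPolicy == "imputed" && any(st$category == "DD"))
        stop("imputed DD policy requires traits for imputation")
      res <- tryCatch(
        monteCarloTest(datasets[[i]]$tree, st, spec, inp$focal,
                       nPerm = config$nPerm, scheme = config$scheme,
                       k = config$k, seed = testSeeds[i, s]),
        error = function(e) e)
      if (inherits(res, "error")) {
        detail[[idx]] <- data.frame(dataset = i, scenario = config$scenarios[s],
                                    n_survivors = NA, obs = NA, mean_sim = NA,
                                    sd_sim = NA, p = NA, code = NA,
                                    note = conditionMessage(res))
      } else {
        results[[idx]] <- res
        detail[[idx]] <- data.frame(dataset = i, scenario = config$scenarios[s],
                                    n_survivors = res$nSurvivors,
                                    obs = res$obs, mean_sim = res$meanSim,
                                    sd_sim = res$sdSim, p = res$p,
                                    code = res$code, note = "")
      }
    }
  }
  results <- results[!vapply(results, is.null, logical(1))]
  detail <- do.call(rbind, detail)

  summary <- summarizeEnsemble(results, pooling = config$pooling)
  manifest <- list(
    n_datasets = nData, n_scenarios = nScen, n_perm = config$nPerm,
    n_sim_vectors = sum(vapply(results, function(r) length(r$sim), 0)),
    n_obs_vectors = length(results),
    seed = config$seed, scheme = config$scheme,
    scenarios = config$scenarios, dd_policy = config$ddPolicy,
    dataset_seeds = vapply(datasets, function(d) as.numeric(d$seed), 0))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(config$outDir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(detail, file.path(config$outDir, "results_detail.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(inp$clades)) {
      cs <- cladeSummary(datasets[[1]]$tree, datasets[[1]]$statuses,
                         inp$clades, inp$focal)
      utils::write.csv(cs, file.path(config$outDir, "clades.csv"),
                       row.names = FALSE)
    }
  }
  invisible(list(results = results, detail = detail, summary = summary,
                 manifest = manifest))
}

#' Summarize test results across replicate data sets
#'
#' One row per scenario: mean number of survivors, mean observed rank, the
#' pooled simulated-rank mean and SD, the pooled p-value and its significance
#' code. With `pooling = "mean_p"` the replicate p-values are averaged; with
#' `"pooled_sims"` all simulated ranks are pooled and compared against the
#' mean observed rank.
#'
#' @param results a list of `phyloisoTest` objects (>= 1).
#' @param pooling `"mean_p"` or `"pooled_sims"`.
#' @return a `data.frame` with columns `scenario`, `n_species`, `obs`,
#'   `mean_sim`, `sd_sim`, `p`, `code`.
#' @export
summarizeEnsemble <- function(results, pooling = c("mean_p", "pooled_sims")) {
  pooling <- match.arg(pooling)
  if (!length(results)) stop("no test results to summarize")
  scen <- vapply(results, function(r) paste(r$scenario$doomed, collapse = ","),
                 character(1))
  rows <- lapply(unique(scen), function(sc) {
    rs <- results[scen == sc]
    allSim <- unlist(lapply(rs, function(r) r$sim))
    obsBar <- mean(vapply(rs, function(r) r$obs, 0))
    p <- if (pooling == "mean_p") mean(vapply(rs, function(r) r$p, 0))
         else mean(allSim <= obsBar)
    data.frame(scenario = sc,
               n_species = mean(vapply(rs, function(r) r$nSurvivors, 0)),
               obs = obsBar, mean_sim = mean(allSim), sd_sim = stats::sd(allSim),
               p = p, code = significanceCode(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
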