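#' Run the full profile analysis
#'
#' Orchestrates one reproducible run: simulate (or accept) a cohort,
#' preprocess it, fit the LOOCV Lasso per outcome, stability-select the
#' profile, score subjects, evaluate by held-out and score correlations,
#' optionally repeat with covariate adjustment, and assemble the report
#' tables plus a manifest of seeds, versions and stage fingerprints.
#'
#' @param cohort an existing \linkS4class{LipoproteinCohort}; if `NULL`, one
#'   is simulated from `config`.
#' @param config a [cohortConfig()] used when simulating.
#' @param lasso a [lassoConfig()].
#' @param outcomes outcomes to model (default all three).
#' @param adjusted also run the covariate-adjusted sensitivity analysis.
#' @param seed master seed; the simulate/preprocess/fit stages derive their
#'   streams from it (the `lasso` config's own seed is overridden).
#' @param outDir if non-NULL, [renderReports()] writes the artifacts there.
#' @param preprocessArgs extra arguments for [preprocessCohort()].
#' @return (invisibly, when `outDir` is set) a list with elements `cohort`,
#'   `dataset`, `fits` (per outcome: trace, model, score, evaluation, and
#'   the adjusted counterparts if requested), `evaluationTable`,
#'   `coefficientReport`, `manifest`.
#' @examples
#' \donttest{
#' res <- runAnalysis(seed = 1, lasso = lassoConfig(nBoot = 5))
#' res$evaluationTable
#' }
#' @export
runAnalysis <- function(cohort = NULL, config = cohortConfig(),
                        lasso = lassoConfig(), outcomes = outcomeNames(),
                        adjusted = FALSE, seed = 1, outDir = NULL,
                        preprocessArgs = list()) {
  outcomes <- match.arg(outcomes, outcomeNames(), several.ok = TRUE)
  if (is.null(cohort)) cohort <- simulateCohort(config, seed = deriveSeed(seed, 1))
  dataset <- do.call(preprocessCohort,
                     c(list(cohort = cohort, seed = deriveSeed(seed, 2)),
                       preprocessArgs))
  X <- intMatrix(dataset)
  covm <- covariateMatrix(dataset)

  fits <- list()
  for (o in outcomes) {
    y <- outcomeVector(dataset, o)
    cfg <- lasso
    cfg$seed <- deriveSeed(seed, 3 + match(o, outcomeNames()))
    trace <- runLOOCV(X, y, cfg, outcome = o)
    model <- stabilitySelect(trace, cfg$stabilityFraction, average = cfg$average)
    score <- profileScore(X, model)
    evaluation <- evaluateProfile(y, heldoutPredictions(trace),
                                  score = if (length(selectedVariables(model))) score)
    fit <- list(trace = trace, model = model, score = score,
                evaluation = evaluation)
    if (adjusted) {
      acfg <- cfg
      acfg$seed <- deriveSeed(cfg$seed, 77)
      adj <- runAdjusted(X, y, covm, acfg, outcome = o)
      adjScore <- profileScore(X, adj$model)
      fit$adjusted <- c(adj, list(
        score = adjScore,
        evaluation = evaluateProfile(y, heldoutPredictions(adj$trace),
                                     score = if (length(selectedVariables(adj$model))) adjScore)))
    }
    fits[[o]] <- fit
  }

  evalRows <- do.call(rbind, lapply(outcomes, function(o) {
    rows <- cbind(outcome = o, model = "unadjusted", fits[[o]]$evaluation)
    if (adjusted)
      rows <- rbind(rows, cbind(outcome = o, model = "adjusted",
                                fits[[o]]$adjusted$evaluation))
    rows
  }))
  manifest <- list(
    package = as.character(utils::packageVersion("LipoProfile")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    stageSeeds = list(simulate = deriveSeed(seed, 1),
                      preprocess = deriveSeed(seed, 2),
                      fit = stats::setNames(deriveSeed(seed, 3 + seq_along(outcomeNames())),
                                            outcomeNames())),
    cohortConfig = unclass(config)[c("nSubjects", "classBlockRho", "targetR",
                                     "missingRateMean", "missingRateMax")],
    lassoConfig = unclass(lasso),
    stageHashes = list(cohort = stageHash(assay(cohort, "concentrations")),
                       dataset = stageHash(assay(dataset, "int")),
                       heldout = stageHash(lapply(fits, function(f) f$trace@heldout))))
  results <- list(cohort = cohort, dataset = dataset, fits = fits,
                  evaluationTable = evalRows,
                  coefficientReport = coefficientReport(fits),
                  manifest = manifest)
  if (!is.null(outDir)) {
    renderReports(results, outDir)
    return(invisible(results))
  }
  results
}

# Signed coefficient ranking across outcomes, for plot-ready reporting.
coefficientReport <- function(fits) {
  rows <- lapply(names(fits), function(o) {
    m <- fits[[o]]$model
    sel <- selectedVariables(m)
    if (length(sel) == 0)
      return(data.frame(outcome = o, variable = "(no stable profile)",
                        weight = NA_real_, side = NA_character_,
                        retained = NA_integer_))
    w <- profileWeights(m)
    ord <- order(w, decreasing = TRUE)
    data.frame(outcome = o, variable = sel[ord], weight = unname(w[ord]),
               side = ifelse(w[ord] >= 0, "positive", "negative"),
               retained = unname(retentionCounts(m)[sel][ord]))
  })
  do.call(rbind, rows)
}

#' Write report artifacts for a completed run
#'
#' Emits, under `outDir`: `evaluation.csv` (the per-outcome correlation
#' table: r, Fisher 95% CI, p, RMSE, n, at 3-dp rounding),
#' `coefficient_ranking.csv` (variables ranked by signed averaged
#' coefficient with retention counts), one `profile_<outcome>.json` per
#' outcome (selected set, weights, intervals, counts), and
#' `manifest.json`. Re-rendering the same results object writes
#' byte-identical files.
#'
#' @param results a [runAnalysis()] result list.
#' @param outDir output directory (created if absent).
#' @return `outDir`, invisibly.
#' @export
renderReports <- function(results, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  et <- results$evaluationTable
  num <- vapply(et, is.numeric, TRUE) & colnames(et) != "n"
  et[num] <- lapply(et[num], round, 3)
  utils::write.csv(et, file.path(outDir, "evaluation.csv"), row.names = FALSE)

  cr <- results$coefficientReport
  cr$weight <- round(cr$weight, 3)
  utils::write.csv(cr, file.path(outDir, "coefficient_ranking.csv"),
                   row.names = FALSE, na = "")

  modelPayload <- function(m, o) {
    list(outcome = o,
         selected = selectedVariables(m),
         weights = as.list(profileWeights(m)),
         ci_lower = as.list(m@ciLower),
         ci_upper = as.list(m@ciUpper),
         retention_counts = as.list(retentionCounts(m)),
         threshold = m@threshold,
         n_iterations = m@nIterations,
         stable_profile = length(selectedVariables(m)) > 0)
  }
  for (o in names(results$fits)) {
    m <- results$fits[[o]]$model
    jsonlite::write_json(modelPayload(m, o),
                         file.path(outDir, paste0("profile_", o, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(results$fits[[o]]$adjusted))
      jsonlite::write_json(modelPayload(results$fits[[o]]$adjusted$model, o),
                           file.path(outDir, paste0("profile_", o, "_adjusted.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(results$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
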