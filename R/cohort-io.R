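#' Read and write cohort tables as CSV
#'
#' The on-disk format is one row per subject: `subject_id` first, then the
#' 12 lipoprotein columns named exactly as in [lipoproteinVocabulary()], the
#' six covariates and the three outcomes. Missing cells are empty.
#'
#' @param cohort a \linkS4class{LipoproteinCohort}.
#' @param path file path.
#' @return `writeCohortCSV()` returns `path` invisibly; `readCohortCSV()`
#'   returns a \linkS4class{LipoproteinCohort}.
#' @export
writeCohortCSV <- function(cohort, path) {
  stopifnot(is(cohort, "LipoproteinCohort"))
  df <- data.frame(subject_id = colnames(cohort),
                   concentrationMatrix(cohort),
                   as.data.frame(colData(cohort))[, c(covariateNames(), outcomeNames())],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("subject_id", lipoproteinVocabulary(), covariateNames(), outcomeNames())
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("cohort CSV lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("subject_id must be unique")
  conc <- as.matrix(df[, lipoproteinVocabulary()])
  rownames(conc) <- df$subject_id
  cd <- DataFrame(df[, c(covariateNames(), outcomeNames())],
                  row.names = df$subject_id)
  methods::new("LipoproteinCohort", SummarizedExperiment(
    assays = list(concentrations = t(conc)), colData = cd))
}
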