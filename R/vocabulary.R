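#' Lipoprotein particle vocabulary
#'
#' The fixed panel of 12 NMR-quantified lipoprotein particle concentrations:
#' three class totals (VLDL-P, LDL-P, HDL-P) and, for each class, the large,
#' medium and small size subclasses. VLDL and LDL particle concentrations are
#' conventionally reported in nmol/L and HDL in µmol/L; units are labels only
#' and never enter the computation (all modeling happens on the rank-normal
#' scale).
#'
#' @return Character vector of the 12 variable names, class totals first
#'   within each class.
#' @examples
#' lipoproteinVocabulary()
#' @export
lipoproteinVocabulary <- function() {
  c("VLDL-P", "L-VLDL-P", "M-VLDL-P", "S-VLDL-P",
    "LDL-P",  "L-LDL-P",  "M-LDL-P",  "S-LDL-P",
    "HDL-P",  "L-HDL-P",  "M-HDL-P",  "S-HDL-P")
}

#' @rdname lipoproteinVocabulary
#' @return `lipoproteinClassTotals()`: the three class-total names.
#' @export
lipoproteinClassTotals <- function() c("VLDL-P", "LDL-P", "HDL-P")

#' @rdname lipoproteinVocabulary
#' @param total a class-total name, e.g. `"HDL-P"`.
#' @return `lipoproteinSubclasses(total)`: the large/medium/small subclass
#'   names of that class.
#' @export
lipoproteinSubclasses <- function(total) {
  stopifnot(total %in% lipoproteinClassTotals())
  paste0(c("L-", "M-", "S-"), total)
}

#' @rdname lipoproteinVocabulary
#' @return `covariateNames()`: the six covariate column names.
#' @export
covariateNames <- function() {
  c("age", "sex", "bmi", "dyslipidemia", "statins", "leisure_pa")
}

#' @rdname lipoproteinVocabulary
#' @return `outcomeNames()`: the three outcome column names (tl, tert,
#'   wrap53).
#' @export
outcomeNames <- function() c("tl", "tert", "wrap53")
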