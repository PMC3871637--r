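#' Published reference estimates from the original mixed-array field study
#'
#' The original daylily/nightlily (\emph{Hemerocallis fulva} x
#' \emph{H. citrina} F2) mixed-array experiment published posterior summaries
#' of the selection-gradient models, the fitness optima derived from them,
#' and the resulting trait-by-measure selection-mode labels. These tables are
#' shipped as package data: they serve as inputs for reproducing the optimum
#' and mode calculations and as fixtures for validating the classification
#' rules (the underlying raw genotype data were never deposited, so the
#' MCMC fits themselves cannot be re-run on the original data).
#'
#' @return list of three data.frames: \code{coefficients} (per pollinator,
#'   measure and trait: posterior mean, SD and 95\% CI of the linear beta
#'   and quadratic gamma coefficients; \code{visits_covariate} rows carry the
#'   visit fixed effect of the efficiency models), \code{optima} (published
#'   z* = -beta/(2 gamma) points with CIs and standardized phenotypic
#'   ranges, in publication reading order), and \code{modes} (the published
#'   trait-by-measure selection-mode grid).
#' @export
reference_estimates <- function() {
  rd <- function(name) utils::read.delim(
    system.file("extdata", name, package = "pollensel", mustWork = TRUE),
    sep = "\t", stringsAsFactors = FALSE)
  list(coefficients = rd("reference_coefficients.tsv"),
       optima = rd("reference_optima.tsv"),
       modes = rd("reference_modes.tsv"))
}
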