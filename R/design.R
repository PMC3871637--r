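# Standardized model designs for the hierarchical Bayesian Poisson fits.

#' Model specification for a selection analysis
#'
#' Four success measures are analysed per pollinator: \code{visits}
#' (attraction; all available flowers, raw counts), \code{acquisition} and
#' \code{donation} (transfer efficiency; visited flowers only, with the
#' number of visits added as a fixed-effect covariate), and \code{combined}
#' (all available flowers).
#'
#' @param measure one of \code{"visits"}, \code{"acquisition"},
#'   \code{"donation"}, \code{"combined"}.
#' @param pollinator \code{"butterfly"} or \code{"hawkmoth"}.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(measure = c("visits", "acquisition", "donation",
                                   "combined"),
                       pollinator = c("butterfly", "hawkmoth")) {
  measure <- match.arg(measure)
  pollinator <- match.arg(pollinator)
  efficiency <- measure %in% c("acquisition", "donation")
  structure(list(measure = measure, pollinator = pollinator,
                 subset = if (efficiency) "visited_only" else "all_flowers",
                 include_visits_covariate = efficiency),
            class = "model_spec")
}

#' Build a standardized design for a selection model
#'
#' Selects the records of the spec's pollinator (and, for efficiency
#' measures, the visited flowers only), standardizes the five floral traits
#' to mean 0 / SD 1 on the analysed subset, squares the standardized traits,
#' and prepares the response: raw visit counts for \code{visits}; for the
#' other measures the success counts are scaled to SD 1 and rounded to the
#' nearest nonnegative integer so the Poisson likelihood stays valid
#' (\code{scale_response = FALSE} keeps raw integer counts instead).
#'
#' @param records tallied success records carrying \code{W} (from
#'   \code{\link{combined_success}}).
#' @param plants plant table with the five trait columns and flower_id.
#' @param spec a \code{\link{model_spec}}.
#' @param scale_response scale non-visit responses to SD 1 before rounding.
#' @return list of class \code{standardized_design}: response \code{y},
#'   fixed-effect matrix \code{X} (intercept, 5 linear, 5 quadratic, visits
#'   covariate when applicable), \code{bout}/\code{genet} grouping indices,
#'   and a \code{transform} record (trait means/SDs, response scale factor,
#'   standardized trait ranges).
#' @export
build_design <- function(records, plants, spec, scale_response = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  rec <- records[records$pollinator == spec$pollinator, , drop = FALSE]
  if (spec$subset == "visited_only")
    rec <- rec[rec$visits >= 1L, , drop = FALSE]
  if (!nrow(rec)) stop("no records for this model spec")
  tr <- as.matrix(plants[match(rec$flower_id, plants$flower_id),
                         trait_names()])
  mu <- colMeans(tr); sd <- apply(tr, 2, stats::sd)
  if (any(sd == 0))
    stop("zero-variance trait: ", trait_names()[which(sd == 0)[1]])
  Z <- sweep(sweep(tr, 2, mu), 2, sd, "/")
  colnames(Z) <- trait_names()
  y_raw <- switch(spec$measure, visits = rec$visits, acquisition = rec$X,
                  donation = rec$Y, combined = rec$W)
  scale_factor <- 1
  y <- y_raw
  if (spec$measure != "visits" && scale_response) {
    s <- stats::sd(y_raw)
    if (s > 0) scale_factor <- 1 / s
    y <- y_raw * scale_factor
  }
  y <- as.integer(round(pmax(y, 0)))
  X <- cbind(alpha = 1, Z, Z^2)
  colnames(X) <- c("alpha", paste0("beta_", trait_names()),
                   paste0("gamma_", trait_names()))
  if (spec$include_visits_covariate)
    X <- cbind(X, beta_visits = as.numeric(rec$visits))
  structure(list(
    y = y, X = X,
    bout = as.integer(factor(rec$bout_id)),
    genet = as.integer(factor(rec$genet_id)),
    bout_levels = levels(factor(rec$bout_id)),
    genet_levels = levels(factor(rec$genet_id)),
    spec = spec,
    transform = list(trait_mean = mu, trait_sd = sd,
                     response_scale = scale_factor,
                     trait_range = apply(Z, 2, range))),
    class = "standardized_design")
}
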