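# Selection-mode classification: CI sign classes, the fitness optimum
# z* = -beta / (2 gamma), and the directional / stabilizing / disruptive
# rules.

#' Classify a coefficient's sign from its posterior draws
#'
#' Negative if the upper bound of the central credible interval is below 0,
#' positive if the lower bound is above 0, otherwise \code{none}. The
#' posterior median supplies the sign direction used in downstream labels.
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param level credible level.
#' @return list: sign (\code{negative}/\code{none}/\code{positive}), lower,
#'   upper, mean, median.
#' @export
classify_coefficient <- function(draws, level = 0.95) {
  if (length(draws) < 100L) stop("need >= 100 draws")
  a <- (1 - level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), names = FALSE)
  sign <- if (q[2] < 0) "negative" else if (q[1] > 0) "positive" else "none"
  list(sign = sign, lower = q[1], upper = q[2], mean = mean(draws),
       median = stats::median(draws))
}

#' Estimate the fitness optimum z* = -beta / (2 gamma)
#'
#' The point estimate uses the posterior-mean coefficients (so printed
#' posterior means reproduce printed optima); the credible interval, when
#' draws are supplied, is formed from the 2.5\%/97.5\% quantiles of the
#' per-draw ratio. The optimum is a maximum when mean gamma < 0 and a
#' minimum when mean gamma > 0.
#'
#' @param beta posterior draws of the linear coefficient, or a scalar
#'   posterior mean.
#' @param gamma posterior draws of the quadratic coefficient, or a scalar.
#' @param phenotypic_range optional (min, max) of the standardized trait in
#'   the analysed flowers.
#' @param level credible level.
#' @param tol smallest |mean gamma| for which the optimum is defined.
#' @return list of class \code{optimum_estimate}: z_star, ci_lower, ci_upper
#'   (NA without draws), kind (\code{maximum}/\code{minimum}),
#'   phenotypic_range, ci_within_range (NA when either is unavailable).
#' @export
estimate_optimum <- function(beta, gamma, phenotypic_range = NULL,
                             level = 0.95, tol = 1e-8) {
  mb <- mean(beta); mg <- mean(gamma)
  if (abs(mg) < tol) stop("undefined optimum: posterior-mean gamma is ~0")
  z <- -mb / (2 * mg)
  ci <- c(NA_real_, NA_real_)
  if (length(beta) > 1L && length(gamma) > 1L) {
    a <- (1 - level) / 2
    ratio <- -beta / (2 * gamma)
    ci <- stats::quantile(ratio, c(a, 1 - a), names = FALSE)
  }
  within <- if (anyNA(ci) || is.null(phenotypic_range)) NA
    else ci[1] >= phenotypic_range[1] && ci[2] <= phenotypic_range[2]
  structure(list(z_star = z, ci_lower = ci[1], ci_upper = ci[2],
                 kind = if (mg < 0) "maximum" else "minimum",
                 phenotypic_range = phenotypic_range,
                 ci_within_range = within),
            class = "optimum_estimate")
}

#' @export
print.optimum_estimate <- function(x, ...) {
  cat(sprintf("Fitness %s at z* = %.3f", x$kind, x$z_star))
  if (!is.na(x$ci_lower))
    cat(sprintf(" (95%% CI %.3f to %.3f)", x$ci_lower, x$ci_upper))
  if (!is.null(x$phenotypic_range))
    cat(sprintf("; phenotypic range %.3f to %.3f", x$phenotypic_range[1],
                x$phenotypic_range[2]))
  cat("\n")
  invisible(x)
}

#' Classify the mode of selection on a trait
#'
#' Rules, applied in order: (a) quadratic coefficient classified negative
#' and the z* CI within the phenotypic range -> stabilizing; (b) quadratic
#' positive and z* CI within range -> disruptive; (c) quadratic classified
#' but the z* CI exceeds the range -> \code{stabilizing_or_directional}
#' (direction from the sign of the linear coefficient's posterior median);
#' (d) only the linear coefficient classified -> directional; (e) neither
#' classified -> none.
#'
#' @param sign_linear,sign_quadratic sign classes from
#'   \code{\link{classify_coefficient}}.
#' @param z_ci numeric (lower, upper) z* credible bounds; required when the
#'   quadratic term is classified.
#' @param phenotypic_range numeric (min, max) of the standardized trait.
#' @param linear_direction sign of the linear coefficient's posterior median
#'   (+1/-1), used for direction labels even when its CI spans 0.
#' @return list: mode (\code{none}/\code{directional}/\code{stabilizing}/
#'   \code{disruptive}/\code{stabilizing_or_directional}) and direction
#'   (\code{increasing}/\code{decreasing}/NA).
#' @export
classify_mode <- function(sign_linear, sign_quadratic, z_ci = NULL,
                          phenotypic_range = NULL, linear_direction = NULL) {
  dir_of <- function() {
    if (!is.null(linear_direction) && is.finite(linear_direction) &&
        linear_direction != 0)
      return(if (linear_direction > 0) "increasing" else "decreasing")
    NA_character_
  }
  if (sign_quadratic != "none") {
    if (is.null(z_ci) || is.null(phenotypic_range) || anyNA(z_ci))
      stop("z* CI and phenotypic range required when the quadratic term is classified")
    within <- z_ci[1] >= phenotypic_range[1] && z_ci[2] <= phenotypic_range[2]
    if (within)
      return(list(mode = if (sign_quadratic == "negative") "stabilizing"
                         else "disruptive",
                  direction = NA_character_))
    return(list(mode = "stabilizing_or_directional", direction = dir_of()))
  }
  if (sign_linear != "none")
    return(list(mode = "directional", direction = dir_of()))
  list(mode = "none", direction = NA_character_)
}

#' Classify selection on every trait of a fitted model
#'
#' Applies \code{\link{classify_coefficient}}, \code{\link{estimate_optimum}}
#' and \code{\link{classify_mode}} to each of the five floral traits of a
#' \code{selfit}, using the standardized phenotypic ranges recorded in the
#' design.
#'
#' @param fit a \code{selfit}.
#' @param level credible level.
#' @return data.frame: trait, measure, pollinator, sign_linear,
#'   sign_quadratic, beta_mean, gamma_mean, z_star, z_lower, z_upper,
#'   range_min, range_max, mode, direction.
#' @export
classify_selection <- function(fit, level = 0.95) {
  M <- draw_matrix(fit)
  rng <- fit$design$transform$trait_range
  rows <- lapply(trait_names(), function(tr) {
    b <- M[, paste0("beta_", tr)]
    g <- M[, paste0("gamma_", tr)]
    cb <- classify_coefficient(b, level)
    cg <- classify_coefficient(g, level)
    pr <- rng[, tr]
    z <- list(z_star = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_)
    if (abs(mean(g)) > 1e-8)
      z <- estimate_optimum(b, g, phenotypic_range = pr, level = level)
    md <- classify_mode(cb$sign, cg$sign,
                        z_ci = c(z$ci_lower, z$ci_upper),
                        phenotypic_range = pr,
                        linear_direction = sign(cb$median))
    data.frame(trait = tr, measure = fit$design$spec$measure,
               pollinator = fit$design$spec$pollinator,
               sign_linear = cb$sign, sign_quadratic = cg$sign,
               beta_mean = cb$mean, gamma_mean = cg$mean,
               z_star = z$z_star, z_lower = z$ci_lower,
               z_upper = z$ci_upper, range_min = pr[1], range_max = pr[2],
               mode = md$mode, direction = md$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize selection classifications as a trait-by-measure grid
#'
#' @param classifications data.frame(s) from \code{\link{classify_selection}}
#'   (rows from several fits may be concatenated).
#' @return data.frame: pollinator, trait, one column per measure holding the
#'   mode label (annotated with the direction where one applies).
#' @export
summarize_selection <- function(classifications) {
  cl <- classifications
  lab <- ifelse(is.na(cl$direction) | cl$mode %in% c("none", "stabilizing",
                                                     "disruptive"),
                cl$mode, paste0(cl$mode, " (", cl$direction, ")"))
  lab[cl$mode == "none"] <- "ns"
  cl$label <- lab
  measures <- intersect(c("visits", "acquisition", "donation", "combined"),
                        unique(cl$measure))
  out <- unique(cl[, c("pollinator", "trait")])
  for (m in measures) {
    sub <- cl[cl$measure == m, , drop = FALSE]
    out[[m]] <- sub$label[match(paste(out$pollinator, out$trait),
                                paste(sub$pollinator, sub$trait))]
  }
  rownames(out) <- NULL
  out
}
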