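# Per-flower-per-bout pollination success: visits (attraction), outcross
# grains acquired X (maternal success), grains donated Y (paternal success),
# and the combined statistic W = X + Y * (Ave.X / Ave.Y).

#' Tally visits, pollen acquisition and pollen donation
#'
#' For every flower available during a bout: \code{visits} is the number of
#' occurrences in the bout's visit sequence; \code{X} counts outcross grains
#' on its stigma (by default including outcross grains whose donor could not
#' be assigned -- they are still outcross pollen acquired); \code{Y} counts
#' grains on other stigmas in the same bout assigned (strict or relaxed) to
#' the flower's genet. Unvisited flowers get zero rows.
#'
#' @param assignments data.frame from \code{\link{assign_paternity}}.
#' @param exp a \code{pollen_experiment}.
#' @param x_counts \code{"all_outcross"} (default) or
#'   \code{"assigned_only"}: whether X includes donor-unassigned outcross
#'   grains.
#' @return data.frame: flower_id, genet_id, bout_id, pollinator, visits, X, Y.
#' @export
tally_success <- function(assignments, exp,
                          x_counts = c("all_outcross", "assigned_only")) {
  x_counts <- match.arg(x_counts)
  if (nrow(assignments) &&
      !all(assignments$stigma_flower_id %in% exp$plants$flower_id))
    stop("assignment references unknown flower")
  bout_ids <- unique(exp$bouts$bout_id)
  pol <- vapply(bout_ids, function(b)
    exp$bouts$pollinator[exp$bouts$bout_id == b][1], "")
  rows <- list()
  for (b in bout_ids) {
    fl <- flowers_available(exp, b)
    df <- data.frame(flower_id = fl,
                     genet_id = exp$plants$genet_id[
                       match(fl, exp$plants$flower_id)],
                     bout_id = b, pollinator = pol[[b]],
                     stringsAsFactors = FALSE)
    vseq <- exp$bouts$flower_id[exp$bouts$bout_id == b]
    df$visits <- as.integer(tabulate(match(vseq, fl), nbins = length(fl)))
    a <- assignments[assignments$bout_id == b, , drop = FALSE]
    outcross <- a[a$category != "self", , drop = FALSE]
    xa <- if (x_counts == "all_outcross") outcross
          else outcross[outcross$category != "unassigned", , drop = FALSE]
    df$X <- as.integer(tabulate(match(xa$stigma_flower_id, fl),
                                nbins = length(fl)))
    donated <- outcross[!is.na(outcross$donor_id), , drop = FALSE]
    df$Y <- as.integer(tabulate(match(donated$donor_id, df$genet_id),
                                nbins = length(fl)))
    rows[[b]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combined pollination success W
#'
#' \eqn{W = X + Y (Ave.X / Ave.Y)}, with the ratio computed per pollinator
#' class across all its records; the \code{unity} mode sets the ratio to 1
#' (no pollen competition: every deposited outcross grain could sire an
#' ovule), i.e. \eqn{W = X + Y}.
#'
#' @param records data.frame from \code{\link{tally_success}}.
#' @param mode \code{"observed_ratio"} or \code{"unity"}.
#' @return list: \code{records} (input plus a \code{W} column) and
#'   \code{summary} data.frame (pollinator, ave_X, ave_Y, ratio).
#' @export
combined_success <- function(records,
                             mode = c("observed_ratio", "unity")) {
  mode <- match.arg(mode)
  sums <- list()
  records$W <- NA_real_
  for (p in unique(records$pollinator)) {
    sel <- records$pollinator == p
    ave_x <- mean(records$X[sel]); ave_y <- mean(records$Y[sel])
    ratio <- if (mode == "unity") 1 else {
      if (ave_y == 0)
        stop("ave_Y is 0 for pollinator ", p,
             " in observed_ratio mode; use mode = 'unity'")
      ave_x / ave_y
    }
    records$W[sel] <- records$X[sel] + records$Y[sel] * ratio
    sums[[p]] <- data.frame(pollinator = p, ave_X = ave_x, ave_Y = ave_y,
                            ratio = ratio, stringsAsFactors = FALSE)
  }
  list(records = records, summary = do.call(rbind, sums))
}
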