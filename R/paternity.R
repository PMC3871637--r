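# Haploid-gamete paternity: self/outcross classification, exclusion plus
# LOD/Delta likelihood assignment, and simulation-calibrated confidence
# thresholds.
#
# Likelihood model per locus: the grain carries allele a, the candidate has
# genotype G, and the population frequency of a is p_a. With typing-error
# rate e the per-locus likelihood ratio is ((1-e) T(a|G) + e p_a) / p_a where
# T(a|G) is the gamete transmission probability (1 for a homozygote a/a, 0.5
# for a heterozygote carrying a, 0 otherwise). The LOD score is the sum of
# the natural-log ratios over loci typed in both grain and candidate.

# Wide haploid matrix (grain x locus) from a long grain table; post-QC grains
# carry at most one allele per locus.
grain_matrix <- function(grains, panel) {
  loci <- names(panel)
  ids <- unique(grains$grain_id)
  M <- matrix(NA_integer_, length(ids), length(loci),
              dimnames = list(ids, loci))
  nall <- lengths(grains$alleles)
  if (any(nall > 1L))
    stop("grain table contains multi-allele observations; run discard_multiallelic first")
  one <- nall == 1L
  M[cbind(match(grains$grain_id[one], ids),
          match(grains$locus[one], loci))] <-
    unlist(grains$alleles[one], use.names = FALSE)
  M
}

# Diploid lookup matrices (genet x locus) for allele1/allele2.
genotype_matrices <- function(genotypes, panel) {
  loci <- names(panel)
  genets <- unique(genotypes$genet_id)
  A1 <- matrix(NA_integer_, length(genets), length(loci),
               dimnames = list(genets, loci))
  A2 <- A1
  idx <- cbind(match(genotypes$genet_id, genets),
               match(genotypes$locus, loci))
  A1[idx] <- genotypes$allele1
  A2[idx] <- genotypes$allele2
  list(A1 = A1, A2 = A2)
}

#' Classify a pollen grain as self or outcross
#'
#' A grain is self if, at every locus typed in both the grain and the
#' maternal plant, its allele occurs in the maternal genotype (the species
#' are self-incompatible, so self grains never sire seed, but they do land
#' on stigmas). Loci missing in either party are skipped; a grain with no
#' comparable locus is classed self by this rule and flagged.
#'
#' @param grain named integer vector (one allele per locus, NA = untyped).
#' @param maternal list with \code{a1}, \code{a2}: named integer vectors of
#'   the maternal diploid genotype.
#' @return \code{"self"} or \code{"outcross"}, with attribute
#'   \code{n_comparable} (number of loci compared).
#' @export
classify_self <- function(grain, maternal) {
  comp <- !is.na(grain) & !is.na(maternal$a1[names(grain)])
  n <- sum(comp)
  ok <- grain[comp] == maternal$a1[names(grain)][comp] |
        grain[comp] == maternal$a2[names(grain)][comp]
  structure(if (all(ok)) "self" else "outcross", n_comparable = n)
}

#' Candidate pollen donors for a grain
#'
#' Candidates are the distinct genets of flowers occupying visit positions
#' strictly before the grain's deposition visit within the same trip bout,
#' excluding the maternal genet. The deposition visit is the first visit to
#' the stigma flower unless \code{visit_index} is supplied.
#'
#' @param stigma_flower_id the grain's stigma flower.
#' @param bout_visits data.frame of the bout's visits, ordered by
#'   \code{visit_order}, with columns flower_id and genet_id.
#' @param maternal_genet the stigma flower's genet.
#' @param visit_index optional 1-based deposition visit position.
#' @return character vector of candidate genet ids (first-visit order).
#' @export
candidate_donors <- function(stigma_flower_id, bout_visits, maternal_genet,
                             visit_index = NULL) {
  pos <- which(bout_visits$flower_id == stigma_flower_id)
  if (!length(pos)) stop("stigma flower not visited in this bout: ",
                         stigma_flower_id)
  dep <- if (is.null(visit_index)) pos[1] else visit_index
  before <- bout_visits$genet_id[seq_len(dep - 1L)]
  setdiff(unique(before), maternal_genet)
}

#' LOD score of a candidate donor for a haploid grain
#'
#' @param grain named integer vector (one allele per locus, NA = untyped).
#' @param candidate list(a1, a2) named integer vectors (diploid genotype).
#' @param freqs an \code{allele_freqs} table covering all observed alleles.
#' @param e typing-error rate in [0, 1).
#' @return the LOD score (natural log), summed over loci typed in both.
#' @export
lod_score <- function(grain, candidate, freqs, e = 0.01) {
  stopifnot(e >= 0, e < 1)
  total <- 0
  for (loc in names(grain)) {
    a <- grain[[loc]]
    c1 <- candidate$a1[[loc]]; c2 <- candidate$a2[[loc]]
    if (is.na(a) || is.na(c1)) next
    p <- freqs[[loc]][as.character(a)]
    if (is.na(p) || p <= 0)
      stop("allele ", a, " at locus ", loc,
           " has no entry in the frequency table")
    T <- ((c1 == a) + (c2 == a)) / 2
    total <- total + log(((1 - e) * T + e * p) / p)
  }
  unname(total)
}

#' Delta statistic of a set of candidate LOD scores
#'
#' Difference between the LOD of the most likely and the second most likely
#' candidate; with a single candidate, Delta is that candidate's LOD.
#'
#' @param lods numeric vector of candidate LOD scores (>= 1 value).
#' @return Delta (0 for tied leaders).
#' @export
delta_stat <- function(lods) {
  if (!length(lods)) stop("empty LOD set")
  if (length(lods) == 1L) return(lods[[1]])
  s <- sort(lods, decreasing = TRUE)
  s[1] - s[2]
}

#' Calibration settings for Delta confidence thresholds
#'
#' Defaults mirror a standard parentage-simulation setup for this kind of
#' array experiment: 10,000 cycles, 473 candidate parents, 90\% of candidates
#' sampled, all loci typed, 1\% typing error, 80\% relaxed and 95\% strict
#' confidence.
#'
#' @param cycles number of simulated assignment cycles.
#' @param n_candidates candidate-parent population size.
#' @param prop_sampled probability that the true father is among candidates.
#' @param prop_loci_typed per-locus typing probability of the test gamete.
#' @param error typing-error rate e.
#' @param confidence_levels confidence levels (relaxed, strict).
#' @return list of class \code{calibration_config}.
#' @export
calibration_config <- function(cycles = 10000L, n_candidates = 473L,
                               prop_sampled = 0.90, prop_loci_typed = 1.00,
                               error = 0.01,
                               confidence_levels = c(0.80, 0.95)) {
  stopifnot(cycles >= 1L, n_candidates >= 2L,
            prop_sampled >= 0, prop_sampled <= 1,
            prop_loci_typed >= 0, prop_loci_typed <= 1,
            error >= 0, error < 1)
  structure(list(cycles = as.integer(cycles),
                 n_candidates = as.integer(n_candidates),
                 prop_sampled = prop_sampled,
                 prop_loci_typed = prop_loci_typed, error = error,
                 confidence_levels = sort(confidence_levels)),
            class = "calibration_config")
}

#' Calibrate Delta confidence thresholds by Monte-Carlo simulation
#'
#' Each cycle draws a true father from Hardy--Weinberg proportions at the
#' population allele frequencies, generates one haploid gamete with typing
#' error and partial typing, draws \code{n_candidates - 1} unrelated
#' candidates, includes the true father with probability
#' \code{prop_sampled}, scores every candidate, and records the Delta of the
#' most likely candidate together with whether it is the true father. The
#' threshold for each confidence level is the smallest Delta* such that the
#' fraction of correct assignments among cycles with Delta >= Delta* reaches
#' the level.
#'
#' @param freqs an \code{allele_freqs} table.
#' @param calib a \code{\link{calibration_config}}.
#' @param seed integer seed.
#' @return list of class \code{delta_thresholds}: \code{relaxed},
#'   \code{strict}, a \code{summary} data.frame (level, threshold,
#'   assignment_rate, accuracy), and the per-cycle \code{cycles} table
#'   (delta, correct) for external validation.
#' @export
calibrate_delta <- function(freqs, calib = calibration_config(), seed = 1L) {
  set.seed(seed)
  loci <- names(freqs)
  n <- calib$cycles
  C <- calib$n_candidates
  e <- calib$error
  delta <- numeric(n); correct <- logical(n)
  chunk <- max(1L, min(n, as.integer(2e6 / C)))
  done <- 0L
  while (done < n) {
    m <- min(chunk, n - done)
    LOD <- matrix(0, m, C)   # column C is the true father
    typedany <- logical(m)
    for (loc in loci) {
      p <- freqs[[loc]]
      K <- length(p)
      fa1 <- sample.int(K, m, replace = TRUE, prob = p)
      fa2 <- sample.int(K, m, replace = TRUE, prob = p)
      g <- ifelse(stats::runif(m) < 0.5, fa1, fa2)
      err <- stats::runif(m) < e
      if (any(err))
        g[err] <- sample.int(K, sum(err), replace = TRUE, prob = p)
      typed <- stats::runif(m) < calib$prop_loci_typed
      if (!any(typed)) next
      typedany <- typedany | typed
      ca1 <- matrix(sample.int(K, m * (C - 1L), replace = TRUE, prob = p),
                    m, C - 1L)
      ca2 <- matrix(sample.int(K, m * (C - 1L), replace = TRUE, prob = p),
                    m, C - 1L)
      Tc <- cbind((ca1 == g) + (ca2 == g), (fa1 == g) + (fa2 == g)) / 2
      pg <- p[g]
      contrib <- log(((1 - e) * Tc + e * pg) / pg)
      LOD <- LOD + contrib * typed
    }
    sampled <- stats::runif(m) < calib$prop_sampled
    LOD[!sampled, C] <- -Inf
    i1 <- max.col(LOD, ties.method = "first")
    l1 <- LOD[cbind(seq_len(m), i1)]
    LOD[cbind(seq_len(m), i1)] <- -Inf
    l2 <- LOD[cbind(seq_len(m), max.col(LOD, ties.method = "first"))]
    idx <- done + seq_len(m)
    delta[idx] <- ifelse(is.finite(l2), l1 - l2, l1)
    correct[idx] <- sampled & (i1 == C) & typedany
    done <- done + m
  }
  ord <- order(delta, decreasing = TRUE)
  acc <- cumsum(correct[ord]) / seq_len(n)
  dsort <- delta[ord]
  pick <- function(level) {
    ok <- which(acc >= level)
    if (!length(ok)) {
      warning("confidence level ", level,
              " unreachable; threshold set to +Inf")
      return(Inf)
    }
    # accuracy holds over all cycles: any nonnegative Delta qualifies
    if (max(ok) == n) return(0)
    dsort[max(ok)]
  }
  lev <- calib$confidence_levels
  thr <- vapply(lev, pick, 0)
  summary <- data.frame(
    level = lev, threshold = thr,
    assignment_rate = vapply(thr, function(t) mean(delta >= t), 0),
    accuracy = vapply(thr, function(t)
      if (any(delta >= t)) mean(correct[delta >= t]) else NA_real_, 0))
  structure(list(relaxed = thr[[1]], strict = thr[[length(thr)]],
                 summary = summary, calib = calib,
                 cycles = data.frame(delta = delta, correct = correct)),
            class = "delta_thresholds")
}

#' @export
print.delta_thresholds <- function(x, ...) {
  cat("Delta confidence thresholds (", x$calib$cycles, " cycles, ",
      x$calib$n_candidates, " candidates)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Exclusion + likelihood assignment for one grain. Internal; use
# assign_paternity for the full per-experiment pipeline.
assign_one <- function(grain, maternal, cand_ids, geno, freqs, thresholds,
                       e, mismatch_tolerance = 0L) {
  res <- list(category = "unassigned", donor_id = NA_character_,
              best_lod = NA_real_, delta = NA_real_,
              n_candidates = length(cand_ids))
  if (classify_self(grain, maternal) == "self") {
    res$category <- "self"
    return(res)
  }
  if (!length(cand_ids)) return(res)
  # simple exclusion: a candidate survives if it mismatches (T = 0) at no
  # more than mismatch_tolerance loci typed in both
  typed <- names(grain)[!is.na(grain)]
  keep <- vapply(cand_ids, function(cid) {
    a1 <- geno$A1[cid, typed]; a2 <- geno$A2[cid, typed]
    comp <- !is.na(a1)
    mism <- sum(grain[typed][comp] != a1[comp] &
                grain[typed][comp] != a2[comp])
    mism <= mismatch_tolerance
  }, TRUE)
  cand_ids <- cand_ids[keep]
  if (!length(cand_ids)) return(res)
  lods <- vapply(cand_ids, function(cid)
    lod_score(grain, list(a1 = geno$A1[cid, ], a2 = geno$A2[cid, ]),
              freqs, e), 0)
  best <- which.max(lods)
  res$donor_id <- cand_ids[[best]]
  res$best_lod <- lods[[best]]
  res$delta <- delta_stat(lods)
  res$category <-
    if (res$delta >= thresholds$strict) "assigned_strict"
    else if (res$delta >= thresholds$relaxed) "assigned_relaxed"
    else "unassigned"
  if (res$category == "unassigned") res$donor_id <- NA_character_
  res
}

#' Assign paternity to every QC-passing pollen grain
#'
#' Per grain: (1) self/outcross classification against the maternal genotype;
#' (2) candidate donors = genets visited strictly before the deposition visit
#' in the same bout; (3) simple exclusion (zero mismatch tolerance by
#' default); (4) likelihood assignment of the surviving candidates by LOD,
#' with confidence from Delta against the calibrated thresholds.
#'
#' @param exp a \code{pollen_experiment}.
#' @param grains long grain data.frame of QC-passing haploid observations.
#' @param freqs an \code{allele_freqs} table.
#' @param thresholds a \code{delta_thresholds} object.
#' @param e typing-error rate used in the LOD model.
#' @param mismatch_tolerance loci a candidate may mismatch and survive
#'   exclusion (default 0).
#' @param visit_index optional named integer vector (grain_id -> 1-based
#'   deposition visit within the bout), e.g. from a simulator's ground-truth
#'   table; by default the deposition visit is taken to be the first visit
#'   to the stigma flower.
#' @return data.frame, one row per grain: grain_id, bout_id,
#'   stigma_flower_id, maternal_genet, category (\code{self},
#'   \code{assigned_strict}, \code{assigned_relaxed}, \code{unassigned}),
#'   donor_id, best_lod, delta, n_candidates.
#' @export
assign_paternity <- function(exp, grains, freqs, thresholds, e = 0.01,
                             mismatch_tolerance = 0L, visit_index = NULL) {
  G <- grain_matrix(grains, exp$panel)
  geno <- genotype_matrices(exp$genotypes, exp$panel)
  meta <- grain_summary(grains)
  meta <- meta[match(rownames(G), meta$grain_id), , drop = FALSE]
  flower2genet <- stats::setNames(exp$plants$genet_id, exp$plants$flower_id)
  bout_split <- split(exp$bouts, exp$bouts$bout_id)
  cand_cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(G))
  for (i in seq_len(nrow(G))) {
    bid <- meta$bout_id[i]; fid <- meta$stigma_flower_id[i]
    mg <- flower2genet[[fid]]
    vi <- if (is.null(visit_index)) NULL
          else unname(visit_index[rownames(G)[i]])
    key <- paste(bid, fid, if (is.null(vi)) "" else vi, sep = "\r")
    if (is.null(cand_cache[[key]])) {
      bv <- bout_split[[bid]]
      bv <- bv[order(bv$visit_order), , drop = FALSE]
      bv$genet_id <- flower2genet[bv$flower_id]
      cand_cache[[key]] <- candidate_donors(fid, bv, mg, visit_index = vi)
    }
    r <- assign_one(G[i, ], list(a1 = geno$A1[mg, ], a2 = geno$A2[mg, ]),
                    cand_cache[[key]], geno, freqs, thresholds, e,
                    mismatch_tolerance)
    out[[i]] <- data.frame(grain_id = rownames(G)[i], bout_id = bid,
                           stigma_flower_id = fid, maternal_genet = mg,
                           category = r$category, donor_id = r$donor_id,
                           best_lod = r$best_lod, delta = r$delta,
                           n_candidates = r$n_candidates,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
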