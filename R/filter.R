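# Grain-level quality control: contamination exclusion, typed-locus
# thresholds, and the per-stigma subsampling cap.

#' Grain QC policy
#'
#' @param min_typed_butterfly minimum typed loci for grains from butterfly
#'   bouts (default 7).
#' @param min_typed_hawkmoth minimum typed loci for grains from hawkmoth bouts
#'   (default 5; the hawkmoth standard is relaxed because those samples
#'   amplify less efficiently).
#' @param stigma_cap maximum grains analysed per stigma (default 72,
#'   approximately twice the number of array plants); larger groups are
#'   subsampled uniformly without replacement.
#' @return list of class \code{filter_policy}.
#' @export
filter_policy <- function(min_typed_butterfly = 7L, min_typed_hawkmoth = 5L,
                          stigma_cap = 72L) {
  stopifnot(stigma_cap >= 1L, min_typed_butterfly >= 0L,
            min_typed_hawkmoth >= 0L)
  structure(list(min_typed_butterfly = as.integer(min_typed_butterfly),
                 min_typed_hawkmoth = as.integer(min_typed_hawkmoth),
                 stigma_cap = as.integer(stigma_cap)),
            class = "filter_policy")
}

#' Per-grain summary of a long grain table
#'
#' @param grains long grain data.frame (grain_id, bout_id, stigma_flower_id,
#'   locus, alleles list column).
#' @return data.frame, one row per grain: grain_id, bout_id,
#'   stigma_flower_id, n_typed (loci with >= 1 allele), multiallelic (any
#'   locus with >= 2 alleles).
#' @export
grain_summary <- function(grains) {
  nall <- lengths(grains$alleles)
  agg <- stats::aggregate(cbind(n_typed = nall >= 1L, multi = nall >= 2L),
                          by = list(grain_id = grains$grain_id,
                                    bout_id = grains$bout_id,
                                    stigma_flower_id = grains$stigma_flower_id),
                          FUN = sum)
  data.frame(grain_id = agg$grain_id, bout_id = agg$bout_id,
             stigma_flower_id = agg$stigma_flower_id,
             n_typed = as.integer(agg$n_typed),
             multiallelic = agg$multi > 0L, stringsAsFactors = FALSE)
}

split_grains <- function(grains, keep_ids) {
  keep <- grains$grain_id %in% keep_ids
  list(kept = grains[keep, , drop = FALSE],
       discarded = grains[!keep, , drop = FALSE])
}

#' Discard grains with multi-allele observations
#'
#' A haploid pollen grain should show at most one allele per locus; 2--3
#' alleles at a locus indicate that several grains were amplified together,
#' and such records are excluded entirely.
#'
#' @param grains long grain data.frame.
#' @return list(kept, discarded), both long grain data.frames.
#' @export
discard_multiallelic <- function(grains) {
  if (!nrow(grains)) return(list(kept = grains, discarded = grains))
  s <- grain_summary(grains)
  split_grains(grains, s$grain_id[!s$multiallelic])
}

#' Filter grains by number of genotyped loci
#'
#' Keeps grains typed at \code{min_typed_butterfly} or more loci
#' (\code{min_typed_hawkmoth} for hawkmoth bouts); the threshold is inclusive.
#'
#' @param grains long grain data.frame of haploid observations.
#' @param bouts bout data.frame (to look up each bout's pollinator).
#' @param policy a \code{\link{filter_policy}}.
#' @return list(kept, discarded).
#' @export
filter_by_typed_loci <- function(grains, bouts, policy = filter_policy()) {
  if (!nrow(grains)) return(list(kept = grains, discarded = grains))
  s <- grain_summary(grains)
  spol <- bouts$pollinator[match(s$bout_id, bouts$bout_id)]
  if (anyNA(spol)) stop("grain references bout with unknown pollinator")
  bad <- setdiff(unique(spol), c("butterfly", "hawkmoth"))
  if (length(bad)) stop("unknown pollinator label: ", bad[1])
  thr <- ifelse(spol == "butterfly", policy$min_typed_butterfly,
                policy$min_typed_hawkmoth)
  split_grains(grains, s$grain_id[s$n_typed >= thr])
}

#' Cap the number of grains analysed per stigma
#'
#' Stigmas bearing \code{stigma_cap} grains or fewer pass unchanged; larger
#' groups are reduced to exactly the cap by uniform sampling without
#' replacement, deterministically for a given seed.
#'
#' @param grains long grain data.frame.
#' @param policy a \code{\link{filter_policy}}.
#' @param seed integer seed.
#' @return list(kept, discarded).
#' @export
subsample_stigma <- function(grains, policy = filter_policy(), seed = 1L) {
  if (!nrow(grains)) return(list(kept = grains, discarded = grains))
  set.seed(seed)
  s <- grain_summary(grains)
  s <- s[order(s$grain_id), , drop = FALSE]
  groups <- split(s$grain_id, paste(s$bout_id, s$stigma_flower_id,
                                    sep = "\r"))
  keep <- unlist(lapply(groups, function(ids) {
    if (length(ids) <= policy$stigma_cap) ids
    else sort(sample(ids, policy$stigma_cap))
  }), use.names = FALSE)
  split_grains(grains, keep)
}

#' Run the full grain QC pipeline
#'
#' Order: per-stigma subsampling cap, contamination (multi-allele) exclusion,
#' then the typed-locus threshold. Discarded grains still appear in the QC
#' report's raw counts but are excluded from all downstream tallies.
#'
#' @param exp a \code{pollen_experiment}.
#' @param policy a \code{\link{filter_policy}}.
#' @param seed integer seed (stigma subsampling).
#' @return list: \code{kept} (long grain data.frame), \code{qc} (per-stigma
#'   report: bout_id, stigma_flower_id, n_raw, n_capped, n_multiallelic,
#'   n_below_threshold, n_kept).
#' @export
filter_grains <- function(exp, policy = filter_policy(), seed = 1L) {
  raw <- grain_summary(exp$grains)
  st1 <- subsample_stigma(exp$grains, policy, seed)
  st2 <- discard_multiallelic(st1$kept)
  st3 <- filter_by_typed_loci(st2$kept, exp$bouts, policy)
  key <- function(s) paste(s$bout_id, s$stigma_flower_id, sep = "\r")
  cnt <- function(g) {
    if (!nrow(g)) return(integer(0))
    s <- grain_summary(g)
    table(key(s))
  }
  keys <- sort(unique(key(raw)))
  tab <- function(g) {
    t <- cnt(g); out <- stats::setNames(integer(length(keys)), keys)
    out[names(t)] <- as.integer(t); out
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  qc <- data.frame(
    bout_id = vapply(parts, `[`, "", 1L),
    stigma_flower_id = vapply(parts, `[`, "", 2L),
    n_raw = tab(exp$grains),
    n_capped = tab(st1$discarded),
    n_multiallelic = tab(st2$discarded),
    n_below_threshold = tab(st3$discarded),
    n_kept = tab(st3$kept),
    stringsAsFactors = FALSE)
  rownames(qc) <- NULL
  list(kept = st3$kept, qc = qc)
}
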