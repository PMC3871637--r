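# -- low-level TSV helpers ----------------------------------------------------

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(sprintf("parse error in %s: missing column(s) %s",
                 basename(path), paste(missing, collapse = ", ")))
  df
}

as_num_col <- function(df, col, path, integer = FALSE, allow_blank = FALSE) {
  x <- df[[col]]
  blank <- !nzchar(trimws(x))
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !blank)
  if (length(bad))
    stop(sprintf("parse error in %s: line %d, column %s: not a number ('%s')",
                 basename(path), bad[1] + 1L, col, x[bad[1]]))
  if (any(blank) && !allow_blank)
    stop(sprintf("parse error in %s: line %d, column %s: blank not allowed",
                 basename(path), which(blank)[1] + 1L, col))
  if (integer) {
    iv <- suppressWarnings(as.integer(x))
    nonint <- which(!is.na(v) & (is.na(iv) | iv != v))
    if (length(nonint))
      stop(sprintf("parse error in %s: line %d, column %s: not an integer ('%s')",
                   basename(path), nonint[1] + 1L, col, x[nonint[1]]))
    v <- iv
  }
  v[blank] <- NA
  v
}

parse_allele_field <- function(x, path, line) {
  if (!nzchar(trimws(x))) return(integer(0))
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  v <- suppressWarnings(as.integer(parts))
  if (anyNA(v) || any(v <= 0L))
    stop(sprintf("parse error in %s: line %d, column alleles: '%s' is not a semicolon-separated list of positive integers",
                 basename(path), line, x))
  v
}

# -- experiment container -----------------------------------------------------

#' Assemble a pollination experiment object
#'
#' Bundles the four cross-referenced tables of a mixed-array pollination
#' experiment (plants with floral traits, diploid genotypes, pollinator trip
#' bouts, and single-pollen-grain observations) plus the marker panel, and
#' validates referential integrity and type invariants.
#'
#' @param plants data.frame: genet_id, flower_id, class
#'   (\code{parental_fulva} or \code{f2_hybrid}), tepal_color, scent_intensity,
#'   corolla_direction, stem_height, asd.
#' @param genotypes data.frame: genet_id, locus, allele1, allele2 (NA = missing
#'   locus).
#' @param bouts data.frame: bout_id, pollinator (\code{butterfly} or
#'   \code{hawkmoth}), visit_order (1-based), flower_id.
#' @param grains long data.frame: grain_id, bout_id, stigma_flower_id, locus,
#'   alleles (list column of integer vectors, possibly empty).
#' @param panel a \code{locus_panel}.
#' @param truth optional ground-truth data.frame from the simulator.
#' @param availability optional data.frame (bout_id, flower_id) restricting
#'   which flowers were present during each bout; \code{NULL} means all.
#' @return An object of class \code{pollen_experiment}.
#' @export
pollen_experiment <- function(plants, genotypes, bouts, grains, panel,
                              truth = NULL, availability = NULL) {
  stopifnot(inherits(panel, "locus_panel"))
  if (anyDuplicated(plants$flower_id))
    stop("flower_id must be unique across plants")
  bad_class <- setdiff(unique(plants$class), c("parental_fulva", "f2_hybrid"))
  if (length(bad_class)) stop("unknown plant class: ", bad_class[1])
  bad_pol <- setdiff(unique(bouts$pollinator), c("butterfly", "hawkmoth"))
  if (length(bad_pol)) stop("unknown pollinator: ", bad_pol[1])

  if (!all(genotypes$genet_id %in% plants$genet_id))
    stop("referential-integrity error: genotype rows for unknown genet_id ",
         setdiff(genotypes$genet_id, plants$genet_id)[1])
  if (!all(genotypes$locus %in% names(panel)))
    stop("genotype rows reference unknown locus ",
         setdiff(genotypes$locus, names(panel))[1])
  # unordered pair convention: store sorted, allele1 <= allele2
  a1 <- genotypes$allele1; a2 <- genotypes$allele2
  if (any(xor(is.na(a1), is.na(a2))))
    stop("genotype rows must have both alleles or neither (missing locus)")
  swap <- !is.na(a1) & a1 > a2
  genotypes$allele1[swap] <- a2[swap]; genotypes$allele2[swap] <- a1[swap]

  if (!all(bouts$flower_id %in% plants$flower_id))
    stop("referential-integrity error: bout visits unknown flower_id ",
         setdiff(bouts$flower_id, plants$flower_id)[1])
  if (nrow(grains)) {
    if (!all(grains$bout_id %in% bouts$bout_id))
      stop("referential-integrity error: grain references unknown bout_id ",
           setdiff(grains$bout_id, bouts$bout_id)[1])
    if (!all(grains$stigma_flower_id %in% plants$flower_id))
      stop("referential-integrity error: grain on unknown flower_id ",
           setdiff(grains$stigma_flower_id, plants$flower_id)[1])
    if (!all(grains$locus %in% names(panel)))
      stop("grain rows reference unknown locus ",
           setdiff(grains$locus, names(panel))[1])
  }
  if (!is.null(availability) &&
      !all(availability$flower_id %in% plants$flower_id))
    stop("availability references unknown flower_id")

  structure(list(plants = plants, genotypes = genotypes, bouts = bouts,
                 grains = grains, panel = panel, truth = truth,
                 availability = availability),
            class = "pollen_experiment")
}

#' @export
print.pollen_experiment <- function(x, ...) {
  cat("Pollination experiment\n")
  gen <- unique(x$plants[, c("genet_id", "class")])
  cat(sprintf("  plants: %d genets (%d parental, %d F2), %d flower records\n",
              nrow(gen), sum(gen$class == "parental_fulva"),
              sum(gen$class == "f2_hybrid"), nrow(x$plants)))
  cat(sprintf("  panel : %d loci\n", length(x$panel)))
  cat(sprintf("  bouts : %d (%s)\n", length(unique(x$bouts$bout_id)),
              paste(unique(x$bouts$pollinator), collapse = ", ")))
  cat(sprintf("  grains: %d records\n", length(unique(x$grains$grain_id))))
  if (!is.null(x$truth)) cat("  ground truth present\n")
  invisible(x)
}

# Flowers present during a bout (all flowers unless restricted).
flowers_available <- function(exp, bout_id) {
  if (is.null(exp$availability)) return(exp$plants$flower_id)
  exp$availability$flower_id[exp$availability$bout_id == bout_id]
}

# -- readers / writers --------------------------------------------------------

#' Read a pollination experiment from tab-separated files
#'
#' Expects \code{plants.tsv}, \code{genotypes.tsv}, \code{bouts.tsv} and
#' \code{grains.tsv} in \code{dir} (schemas as written by
#' \code{\link{write_experiment}}); \code{truth.tsv} and
#' \code{availability.tsv} are read when present.
#'
#' @param dir directory containing the TSV files.
#' @param panel a \code{locus_panel}; if \code{NULL} it is reconstructed from
#'   the alleles seen in \code{genotypes.tsv}.
#' @return A \code{pollen_experiment}.
#' @export
read_experiment <- function(dir, panel = NULL) {
  pp <- file.path(dir, "plants.tsv")
  plants <- read_tsv_checked(pp, c("genet_id", "flower_id", "class",
                                   "tepal_color", "scent_intensity",
                                   "corolla_direction", "stem_height", "asd"))
  for (col in c("tepal_color", "scent_intensity", "corolla_direction",
                "stem_height", "asd"))
    plants[[col]] <- as_num_col(plants, col, pp)

  gp <- file.path(dir, "genotypes.tsv")
  genotypes <- read_tsv_checked(gp, c("genet_id", "locus", "allele1", "allele2"))
  genotypes$allele1 <- as_num_col(genotypes, "allele1", gp, integer = TRUE,
                                  allow_blank = TRUE)
  genotypes$allele2 <- as_num_col(genotypes, "allele2", gp, integer = TRUE,
                                  allow_blank = TRUE)

  bp <- file.path(dir, "bouts.tsv")
  bouts <- read_tsv_checked(bp, c("bout_id", "pollinator", "visit_order",
                                  "flower_id"))
  bouts$visit_order <- as_num_col(bouts, "visit_order", bp, integer = TRUE)
  bouts <- bouts[order(bouts$bout_id, bouts$visit_order), , drop = FALSE]

  grp <- file.path(dir, "grains.tsv")
  grains <- read_tsv_checked(grp, c("grain_id", "bout_id", "stigma_flower_id",
                                    "locus", "alleles"))
  grains$alleles <- lapply(seq_len(nrow(grains)), function(i)
    parse_allele_field(grains$alleles[i], grp, i + 1L))

  truth <- NULL
  tp <- file.path(dir, "truth.tsv")
  if (file.exists(tp)) {
    truth <- read_tsv_checked(tp, c("grain_id", "true_donor_id",
                                    "stigma_flower_id", "bout_id",
                                    "visit_index"))
    truth$visit_index <- as_num_col(truth, "visit_index", tp, integer = TRUE)
  }
  availability <- NULL
  ap <- file.path(dir, "availability.tsv")
  if (file.exists(ap))
    availability <- read_tsv_checked(ap, c("bout_id", "flower_id"))

  if (is.null(panel)) {
    ok <- !is.na(genotypes$allele1)
    al <- split(c(genotypes$allele1[ok], genotypes$allele2[ok]),
                c(genotypes$locus[ok], genotypes$locus[ok]))
    panel <- locus_panel(al)
  }
  pollen_experiment(plants, genotypes, bouts, grains, panel,
                    truth = truth, availability = availability)
}

#' Write a pollination experiment as tab-separated files
#'
#' @param exp a \code{pollen_experiment}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE,
    na = "")
  wt(exp$plants, "plants.tsv")
  wt(exp$genotypes, "genotypes.tsv")
  wt(exp$bouts, "bouts.tsv")
  g <- exp$grains
  g$alleles <- vapply(g$alleles, paste, "", collapse = ";")
  wt(g, "grains.tsv")
  if (!is.null(exp$truth)) wt(exp$truth, "truth.tsv")
  if (!is.null(exp$availability)) wt(exp$availability, "availability.tsv")
  invisible(dir)
}

#' Export the diploid panel in GenePop format
#'
#' Writes the plants' multilocus genotypes as a GenePop file (3-digit allele
#' coding by rank within locus) for interoperability with population-genetics
#' software.
#'
#' @param exp a \code{pollen_experiment}.
#' @param path output file.
#' @export
write_genepop <- function(exp, path) {
  panel <- exp$panel
  code <- lapply(panel, function(a) stats::setNames(sprintf("%03d",
                                                    seq_along(a)), a))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("pollensel diploid panel export", con)
  writeLines(names(panel), con)
  writeLines("Pop", con)
  gsplit <- split(exp$genotypes, exp$genotypes$genet_id)
  for (gid in unique(exp$plants$genet_id)) {
    g <- gsplit[[gid]]
    cells <- vapply(names(panel), function(loc) {
      row <- g[g$locus == loc, , drop = FALSE]
      if (!nrow(row) || is.na(row$allele1[1])) return("000000")
      paste0(code[[loc]][as.character(row$allele1[1])],
             code[[loc]][as.character(row$allele2[1])])
    }, "")
    writeLines(paste0(gid, " ,  ", paste(cells, collapse = " ")), con)
  }
  invisible(path)
}

# -- allele frequencies -------------------------------------------------------

#' Estimate population allele frequencies by copy counting
#'
#' Each plant typed at a locus contributes two allele copies; per-locus copy
#' counts are normalised to relative frequencies. Untyped (missing) loci
#' contribute nothing.
#'
#' @param genotypes genotype data.frame (genet_id, locus, allele1, allele2) or
#'   a \code{pollen_experiment}.
#' @param panel a \code{locus_panel} (taken from the experiment if given one).
#' @return An object of class \code{allele_freqs}: a named list with, per
#'   locus, a named numeric vector of frequencies summing to 1.
#' @export
estimate_allele_frequencies <- function(genotypes, panel = NULL) {
  if (inherits(genotypes, "pollen_experiment")) {
    panel <- genotypes$panel
    genotypes <- genotypes$genotypes
  }
  if (is.null(panel)) stop("panel required")
  out <- vector("list", length(panel)); names(out) <- names(panel)
  for (loc in names(panel)) {
    rows <- genotypes[genotypes$locus == loc & !is.na(genotypes$allele1), ,
                      drop = FALSE]
    if (!nrow(rows)) stop("locus typed in no plant: ", loc)
    copies <- c(rows$allele1, rows$allele2)
    tab <- table(factor(copies, levels = sort(unique(copies))))
    out[[loc]] <- stats::setNames(as.numeric(tab) / sum(tab),
                                  names(tab))
  }
  structure(out, class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat("Allele frequencies for", length(x), "loci\n")
  for (nm in names(x))
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s=%.3f", names(x[[nm]]), x[[nm]]),
                      collapse = " ")))
  invisible(x)
}
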