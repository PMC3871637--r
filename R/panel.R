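#' Marker panel constructors
#'
#' A locus panel describes the codominant microsatellite markers shared by all
#' plants in an experimental array: each locus has a name and a set of integer
#' allele codes (fragment sizes in base pairs).
#'
#' @param alleles named list; one integer vector of allele codes per locus.
#' @return An object of class \code{locus_panel}: a named list of sorted
#'   integer allele vectors.
#' @examples
#' panel <- locus_panel(list(L1 = c(100L, 104L), L2 = c(150L, 152L, 154L)))
#' @export
locus_panel <- function(alleles) {
  if (is.null(names(alleles)) || anyDuplicated(names(alleles)))
    stop("locus names must be present and unique")
  alleles <- lapply(alleles, function(a) {
    a <- as.integer(a)
    if (anyNA(a) || any(a <= 0L)) stop("allele codes must be positive integers")
    sort(unique(a))
  })
  structure(alleles, class = "locus_panel")
}

#' Default 10-locus microsatellite panel
#'
#' Ten loci with 4--8 alleles each. Allele codes are split into two disjoint
#' pools per locus so that the two parental species of a synthetic array carry
#' non-overlapping alleles by default (the first half of each locus' codes are
#' the "parental A" pool, the second half the "parental B" pool).
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus integer vector recycled across loci; each entry
#'   must be an even number >= 4 so both parental pools hold >= 2 alleles.
#' @return A \code{locus_panel}.
#' @export
default_panel <- function(n_loci = 10L, alleles_per_locus = c(4L, 6L, 8L, 6L, 4L, 8L, 6L, 4L, 6L, 8L)) {
  k <- rep_len(as.integer(alleles_per_locus), n_loci)
  if (any(k < 4L) || any(k %% 2L != 0L))
    stop("alleles_per_locus entries must be even and >= 4")
  al <- lapply(seq_len(n_loci), function(i) 100L + 10L * i + 2L * seq_len(k[i]))
  names(al) <- sprintf("L%02d", seq_len(n_loci))
  locus_panel(al)
}

# Disjoint parental allele pools of a panel locus: first half vs second half.
panel_pools <- function(panel) {
  lapply(unclass(panel), function(a) {
    h <- length(a) %/% 2L
    list(A = a[seq_len(h)], B = a[(h + 1L):length(a)])
  })
}

#' @export
print.locus_panel <- function(x, ...) {
  cat("Locus panel:", length(x), "loci\n")
  for (nm in names(x))
    cat(sprintf("  %s: %d alleles (%s)\n", nm, length(x[[nm]]),
                paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
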