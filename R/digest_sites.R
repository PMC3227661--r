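#' Scan a genome for restriction-site motif occurrences
#'
#' Finds every forward-strand occurrence of `motif` (including overlapping
#' ones) in each chromosome.  MluI's recognition sequence ACGCGT is
#' reverse-complement palindromic, so the forward scan is the complete,
#' both-strand site set; the same holds for NlaIII's CATG.
#'
#' @param genome A [Biostrings::DNAStringSet] (named chromosomes) or a named
#'   character vector of sequences.
#' @param motif Recognition sequence, uppercase A/C/G/T only.
#' @param enzyme Optional enzyme name stored with the result.
#' @param cut_offset Bases from motif start to the cut position (MluI cuts
#'   A^CGCGT, offset 1; NlaIII cuts CATG^, offset 4).
#' @return A `RestrictionSiteList`: list with `enzyme`, `motif`,
#'   `cut_offset`, and `sites`, a named list of strictly increasing 0-based
#'   motif start coordinates per chromosome.
#' @export
find_sites <- function(genome, motif, enzyme = motif, cut_offset = 0L) {
  genome <- as_genome(genome)
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    stop("motif must be non-empty and contain only A/C/G/T (no ambiguity codes)")
  }
  hits <- Biostrings::vmatchPattern(motif, genome)
  sites <- lapply(seq_along(genome), function(i) {
    s <- BiocGenerics::start(hits[[i]]) - 1L  # 0-based
    sort(unique(as.integer(s)))
  })
  names(sites) <- names(genome)
  structure(
    list(enzyme = enzyme, motif = motif, cut_offset = as.integer(cut_offset),
         sites = sites),
    class = "RestrictionSiteList"
  )
}

#' @rdname find_sites
#' @export
mlu_sites <- function(genome) find_sites(genome, "ACGCGT", "MluI", cut_offset = 1L)

#' @rdname find_sites
#' @export
nla_sites <- function(genome) find_sites(genome, "CATG", "NlaIII", cut_offset = 4L)

# Coerce character vectors / DNAStringSet to a named DNAStringSet.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
    return(genome)
  }
  if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(genome)
    names(g) <- if (is.null(names(genome))) paste0("chr", seq_along(g)) else names(genome)
    return(g)
  }
  stop("genome must be a DNAStringSet or a named character vector")
}

#' @export
print.RestrictionSiteList <- function(x, ...) {
  n <- sum(vapply(x$sites, length, integer(1)))
  cat(sprintf("RestrictionSiteList: %s (%s, cut +%d), %d sites on %d sequence(s)\n",
              x$enzyme, x$motif, x$cut_offset, n, length(x$sites)))
  invisible(x)
}

#' Total number of sites in a RestrictionSiteList
#' @param x A `RestrictionSiteList`.
#' @return Integer count of sites across all chromosomes.
#' @export
n_sites <- function(x) {
  stopifnot(inherits(x, "RestrictionSiteList"))
  sum(vapply(x$sites, length, integer(1)))
}
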