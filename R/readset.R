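#' Read multiset container
#'
#' Reads are stored collapsed: one row per distinct sequence with its
#' multiplicity.  Optional mean base qualities per distinct sequence
#' support quality filtering.
#'
#' @param seqs Character vector of read sequences (expanded or collapsed).
#' @param counts Multiplicities (defaults to collapsing `seqs`).
#' @param sample_id,condition Sample metadata.
#' @param mean_quality Optional numeric mean Phred quality per row.
#' @return A `ReadSet`.
#' @export
read_set <- function(seqs, counts = NULL, sample_id = NA_character_,
                     condition = NA_character_, mean_quality = NULL) {
  if (is.null(counts)) {
    tab <- table(seqs)
    reads <- data.frame(seq = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  } else {
    stopifnot(length(seqs) == length(counts))
    agg <- tapply(as.integer(counts), seqs, sum)
    reads <- data.frame(seq = names(agg), count = as.integer(agg),
                        stringsAsFactors = FALSE)
  }
  if (any(reads$count < 1L)) stop("multiplicities must be at least 1")
  if (!is.null(mean_quality)) {
    if (length(mean_quality) != nrow(reads)) {
      stop("mean_quality must match the collapsed read rows")
    }
    reads$mean_quality <- mean_quality
  }
  rownames(reads) <- NULL
  structure(list(sample_id = sample_id, condition = condition, reads = reads),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet %s (%s): %d distinct sequences, %d reads\n",
              x$sample_id, x$condition, nrow(x$reads), sum(x$reads$count)))
  invisible(x)
}

#' Total reads in a ReadSet
#' @param x A `ReadSet`.
#' @return Integer total multiplicity.
#' @export
n_reads <- function(x) sum(x$reads$count)

#' Clean a read multiset
#'
#' Removes reads containing N (`drop_n`), reads shorter than `min_len`,
#' reads with mean quality below `min_quality` (only when qualities are
#' present), and - in the erroneous-tag filter used for mRNA tags -
#' sequences whose total multiplicity is 1 (`drop_singletons`).  `dedupe`
#' collapses identical sequences to one representative while keeping the
#' multiplicity as the count; under this container reads are always stored
#' collapsed, so it is accepted for interface completeness and is a no-op.
#'
#' @param rs A [read_set()].
#' @param min_len Minimum read length (0 disables).
#' @param drop_n Drop reads containing N.
#' @param drop_singletons Drop sequences with multiplicity 1.
#' @param dedupe Collapse duplicates (always true of the representation).
#' @param min_quality Mean-quality floor (default Q20); ignored when the
#'   read set carries no qualities.
#' @return Filtered `ReadSet`.
#' @export
filter_reads <- function(rs, min_len = 0L, drop_n = TRUE, drop_singletons = FALSE,
                         dedupe = FALSE, min_quality = 20) {
  stopifnot(inherits(rs, "ReadSet"))
  r <- rs$reads
  keep <- rep(TRUE, nrow(r))
  if (drop_n) keep <- keep & !grepl("N", r$seq, fixed = TRUE)
  if (min_len > 0L) keep <- keep & nchar(r$seq) >= min_len
  if (!is.null(r$mean_quality)) keep <- keep & r$mean_quality >= min_quality
  if (drop_singletons) keep <- keep & r$count > 1L
  r <- r[keep, , drop = FALSE]
  rownames(r) <- NULL
  out <- rs
  out$reads <- r
  out
}

#' Remove tags whose genomic position falls in blacklist annotation
#'
#' Drops mapped tags (protein-coding, repeat, rRNA, tRNA, sn/snoRNA, ...)
#' whose unique genome mapping lies inside any blacklist interval, and
#' tallies removals per category.
#'
#' @param assignments data.frame of mapped tags with `chrom`, `start`,
#'   `end` (0-based half-open) and a `count` column, e.g. mapped rows of
#'   [map_tags()] joined to their library entry coordinates.
#' @param blacklist Named list of data.frames (chrom, start, end), one per
#'   annotation category.
#' @return The retained rows, with a `removed` attribute: named integer
#'   read tallies per category.
#' @export
filter_blacklist <- function(assignments, blacklist) {
  if (!length(blacklist)) {
    attr(assignments, "removed") <- stats::setNames(integer(0), character(0))
    return(assignments)
  }
  gr <- GenomicRanges::GRanges(assignments$chrom,
                               IRanges::IRanges(assignments$start + 1L, assignments$end))
  hit_any <- rep(FALSE, nrow(assignments))
  tallies <- stats::setNames(integer(length(blacklist)), names(blacklist))
  for (cat in names(blacklist)) {
    b <- blacklist[[cat]]
    if (!nrow(b)) next
    bgr <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1L, b$end))
    hit <- IRanges::overlapsAny(gr, bgr)
    tallies[cat] <- sum(assignments$count[hit & !hit_any])
    hit_any <- hit_any | hit
  }
  out <- assignments[!hit_any, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- tallies
  out
}
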