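#' Tag count matrix container
#'
#' Integer tag counts, loci x samples, with per-sample condition labels and
#' library sizes (totals of mapped tags; at least the column sums).
#'
#' @param counts Integer matrix with locus ids as rownames.
#' @param conditions Character vector ("tumor"/"normal") per column.
#' @param library_sizes Per-sample totals; defaults to column sums.
#' @return A `TagCountMatrix`.
#' @export
tag_count_matrix <- function(counts, conditions, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must carry locus ids as rownames")
  if (length(conditions) != ncol(counts)) {
    stop("one condition label per sample column is required")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes < colSums(counts))) {
    stop("library_sizes may not be smaller than the column sums")
  }
  structure(list(counts = counts,
                 samples = data.frame(sample_id = colnames(counts),
                                      condition = conditions,
                                      stringsAsFactors = FALSE),
                 library_sizes = stats::setNames(as.numeric(library_sizes),
                                                 colnames(counts))),
            class = "TagCountMatrix")
}

#' @export
print.TagCountMatrix <- function(x, ...) {
  cat(sprintf("TagCountMatrix: %d loci x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%d %s", table(x$samples$condition),
                            names(table(x$samples$condition))), collapse = ", ")))
  invisible(x)
}

#' Pool replicate libraries of one condition into a single library
#'
#' Per-locus pooled count is the arithmetic mean across the condition's
#' samples, rounded half-up to an integer; the pooled library size is the
#' half-up-rounded mean of the group's library sizes.
#'
#' @param tcm A [tag_count_matrix()].
#' @param condition Condition label to pool.
#' @return List with `counts` (named integer vector per locus) and
#'   `library_size`.
#' @export
pool_by_mean <- function(tcm, condition) {
  stopifnot(inherits(tcm, "TagCountMatrix"))
  sel <- tcm$samples$condition == condition
  if (!any(sel)) stop("no samples with condition '", condition, "'")
  m <- tcm$counts[, sel, drop = FALSE]
  pooled <- round_half_up(rowMeans(m))
  list(counts = stats::setNames(as.integer(pooled), rownames(tcm$counts)),
       library_size = as.integer(round_half_up(mean(tcm$library_sizes[sel]))))
}

#' Write / read a tag count matrix as TSV
#'
#' Plain TSV with a `locus_id` column and one column per sample; a header
#' comment line records conditions and library sizes.
#'
#' @param tcm A [tag_count_matrix()].
#' @param path File path.
#' @export
write_counts_tsv <- function(tcm, path) {
  stopifnot(inherits(tcm, "TagCountMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#condition:%s", paste(tcm$samples$condition, collapse = ",")), con)
  writeLines(sprintf("#library_sizes:%s",
                     paste(format(tcm$library_sizes, scientific = FALSE, trim = TRUE),
                           collapse = ",")), con)
  df <- data.frame(locus_id = rownames(tcm$counts), tcm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  conditions <- strsplit(sub("^#condition:", "", hdr[1]), ",", fixed = TRUE)[[1]]
  libsz <- as.numeric(strsplit(sub("^#library_sizes:", "", hdr[2]), ",", fixed = TRUE)[[1]])
  df <- utils::read.delim(path, skip = 2L, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$locus_id
  tag_count_matrix(m, conditions, libsz)
}
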