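#' Simulate tag reads from a count matrix
#'
#' Each counted tag becomes a single-end read: the library tag sequence
#' (18-mer where available, otherwise the 17-mer) with the adapter appended,
#' then per-base substitution errors at `error_rate`.  An MMSDK locus'
#' count is split between its upstream/downstream tag entries at random.
#' With `error_rate = 0` and an empty adapter the reads are the bare tags
#' and the pipeline recovers the count matrix exactly.  Setting
#' `revcomp_fraction > 0` reverse-complements that fraction of reads to
#' stress orientation-aware mapping.
#'
#' @param library A `VirtualTagLibrary`.
#' @param counts A [tag_count_matrix()]; every locus with a positive count
#'   must have at least one tag entry in `library`.
#' @param adapter Adapter suffix; "" for none, otherwise at least 6 bases.
#' @param error_rate Per-base substitution probability.
#' @param revcomp_fraction Fraction of reads emitted as reverse complements.
#' @param seed Integer seed for splitting, errors and orientation.
#' @return Named list of [read_set()]s, one per sample.
#' @export
simulate_reads <- function(library, counts, adapter = "", error_rate = 0,
                           revcomp_fraction = 0, seed = 1L) {
  stopifnot(inherits(library, "VirtualTagLibrary"), inherits(counts, "TagCountMatrix"))
  if (nzchar(adapter) && nchar(adapter) < 6L) {
    stop("adapter must be empty or at least 6 bases (unclippable otherwise)")
  }
  if (error_rate < 0 || error_rate > 1) stop("error_rate must lie in [0,1]")

  ent <- library$entries
  tagseq <- if (!is.null(ent$tag_18)) ent$tag_18 else ent$tag_17
  by_locus <- split(seq_len(nrow(ent)), ent$locus_id)

  m <- counts$counts
  active <- rownames(m)[rowSums(m) > 0]
  missing <- setdiff(active, names(by_locus))
  if (length(missing)) {
    stop("counted loci lack a tag sequence in the library: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }

  with_seed(stage_seed(seed, "reads"), {
    out <- vector("list", ncol(m))
    names(out) <- colnames(m)
    for (j in seq_len(ncol(m))) {
      cnt <- m[, j]
      cnt <- cnt[cnt > 0]
      if (!length(cnt)) {
        out[[j]] <- read_set(character(0), integer(0),
                             sample_id = colnames(m)[j],
                             condition = counts$samples$condition[j])
        next
      }
      seqs <- character(0)
      mult <- integer(0)
      for (locus in names(cnt)) {
        idx <- by_locus[[locus]]
        n_i <- cnt[[locus]]
        if (length(idx) == 1L) {
          seqs <- c(seqs, tagseq[idx]); mult <- c(mult, n_i)
        } else {
          k <- stats::rbinom(1L, n_i, 0.5)
          seqs <- c(seqs, tagseq[idx[1L]], tagseq[idx[2L]])
          mult <- c(mult, k, n_i - k)
        }
      }
      keep <- mult > 0L
      seqs <- paste0(seqs[keep], adapter)
      mult <- mult[keep]
      reads <- rep(seqs, mult)
      if (error_rate > 0) reads <- mutate_reads(reads, error_rate)
      if (revcomp_fraction > 0) {
        flip <- stats::runif(length(reads)) < revcomp_fraction
        if (any(flip)) reads[flip] <- rev_comp(reads[flip])
      }
      out[[j]] <- read_set(reads, sample_id = colnames(m)[j],
                           condition = counts$samples$condition[j])
    }
    out
  })
}

# independent per-base substitutions; a substituted base never equals the
# original
mutate_reads <- function(reads, rate) {
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Write read sets as FASTQ (constant quality)
#'
#' @param read_sets Named list of [read_set()]s.
#' @param dir Output directory; one `<sample>.fastq` per sample.
#' @return Invisibly, the written paths.
#' @export
write_reads_fastq <- function(read_sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (rs in read_sets) {
    reads <- rep(rs$reads$seq, rs$reads$count)
    path <- file.path(dir, paste0(rs$sample_id, ".fastq"))
    if (length(reads)) {
      x <- Biostrings::DNAStringSet(reads)
      names(x) <- sprintf("%s_read%06d", rs$sample_id, seq_along(x))
      Biostrings::writeXStringSet(x, path, format = "fastq")
    } else {
      file.create(path)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}
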