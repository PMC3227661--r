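#' Genome FASTA I/O
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path File path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read FASTQ reads into a ReadSet
#'
#' @param path FASTQ file.
#' @param sample_id,condition Sample metadata.
#' @return A [read_set()].
#' @export
read_reads_fastq <- function(path, sample_id = basename(path),
                             condition = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  read_set(as.character(x), sample_id = sample_id, condition = condition)
}

#' Export intervals as BED6
#'
#' @param df data.frame with chrom, start, end (0-based half-open) and
#'   optionally name, score, strand.
#' @param path Output file.
#' @export
write_bed6 <- function(df, path) {
  name <- if (!is.null(df$name)) df$name else "."
  score <- if (!is.null(df$score)) df$score else 0
  strand <- if (!is.null(df$strand)) df$strand else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, df$start, df$end,
                   name, format(score, trim = TRUE), strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file.
#' @return data.frame: chrom, start, end (0-based half-open), plus name,
#'   score, strand when present.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- cols[seq_len(min(ncol(df), 6L))]
  df
}

#' Export simulation ground truth as JSON
#'
#' @param truth A `SimTruth` list.
#' @param path Output file.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  if (!is.null(x$gene_models)) x$gene_models <- unclass(x$gene_models)[c("genes", "exons")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a tag library as FASTA
#'
#' Entry ids are `locus_id:side`; the longest available tag form is
#' written.
#'
#' @param library A `VirtualTagLibrary`.
#' @param path Output file.
#' @export
write_library_fasta <- function(library, path) {
  ent <- library$entries
  seqs <- if (!is.null(ent$tag_18)) ent$tag_18 else ent$tag_17
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste(ent$locus_id, ent$side, sep = ":")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write differential records as TSV
#'
#' @param records [call_differential()]-style data.frame.
#' @param path Output file.
#' @export
write_differential_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
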