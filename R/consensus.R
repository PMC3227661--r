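#' miRNA target-consensus filter
#'
#' A (miRNA, gene) pair survives iff it is predicted by at least
#' `min_pred_sources` of the prediction tools (default 2 of the classic 3:
#' DIANA-microT, TargetScan, PicTar supplied as files) AND appears in the
#' union of the experimentally supported databases (at least
#' `min_exp_sources` of them).  Consensus is computed at pair granularity;
#' miRNA ids are normalized case-insensitively with any "hsa-" prefix
#' stripped, and -3p/-5p suffixes are left untouched.
#'
#' @param predictions Named list of data.frames (mirna_id, gene_id), one
#'   per prediction tool; three expected, more allowed.
#' @param experimental Named list of data.frames (mirna_id, gene_id), one
#'   per experimentally supported database.
#' @param min_pred_sources Minimum distinct prediction tools per pair.
#' @param min_exp_sources Minimum distinct experimental sources per pair.
#' @return A `ConsensusResult` data.frame: mirna_id, gene_id,
#'   n_pred_sources, pred_sources, exp_sources.
#' @export
consensus_targets <- function(predictions, experimental, min_pred_sources = 2L,
                              min_exp_sources = 1L) {
  if (!length(predictions) || !length(experimental) ||
      all(!vapply(predictions, nrow, integer(1))) ||
      all(!vapply(experimental, nrow, integer(1)))) {
    warning("empty prediction or experimental input: empty consensus")
    return(empty_consensus())
  }
  if (is.null(names(predictions))) names(predictions) <- paste0("pred", seq_along(predictions))
  if (is.null(names(experimental))) names(experimental) <- paste0("exp", seq_along(experimental))

  norm <- function(df, source) {
    if (!nrow(df)) return(NULL)
    key <- paste(normalize_mirna_id(df$mirna_id), df$gene_id, sep = "\t")
    data.frame(key = unique(key), source = source, stringsAsFactors = FALSE)
  }
  pred <- do.call(rbind, Map(norm, predictions, names(predictions)))
  expr <- do.call(rbind, Map(norm, experimental, names(experimental)))

  pred_n <- tapply(pred$source, pred$key, function(s) length(unique(s)))
  pred_src <- tapply(pred$source, pred$key, function(s) paste(sort(unique(s)), collapse = ";"))
  a_keys <- names(pred_n)[pred_n >= min_pred_sources]

  exp_n <- tapply(expr$source, expr$key, function(s) length(unique(s)))
  exp_src <- tapply(expr$source, expr$key, function(s) paste(sort(unique(s)), collapse = ";"))
  b_keys <- names(exp_n)[exp_n >= min_exp_sources]

  keys <- sort(intersect(a_keys, b_keys))
  if (!length(keys)) return(empty_consensus())
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, `[`, character(1), 2L),
    n_pred_sources = as.integer(pred_n[keys]),
    pred_sources = unname(pred_src[keys]),
    exp_sources = unname(exp_src[keys]),
    stringsAsFactors = FALSE)
  class(out) <- c("ConsensusResult", class(out))
  out
}

empty_consensus <- function() {
  out <- data.frame(mirna_id = character(0), gene_id = character(0),
                    n_pred_sources = integer(0), pred_sources = character(0),
                    exp_sources = character(0), stringsAsFactors = FALSE)
  class(out) <- c("ConsensusResult", class(out))
  out
}

#' Normalize miRNA identifiers
#'
#' Lower-cases and strips a leading "hsa-" prefix; arm suffixes (-3p/-5p)
#' are preserved as-is (no guessing).
#'
#' @param x Character vector of miRNA ids.
#' @return Normalized ids.
#' @export
normalize_mirna_id <- function(x) {
  sub("^hsa-", "", tolower(x))
}

#' Pair consensus targets with differential expression results
#'
#' Restricts consensus pairs to differentially expressed miRNAs, attaches
#' the target gene's differential status, and optionally keeps only
#' anticorrelated pairs (miRNA and target in opposite directions, e.g. a
#' repressed miRNA with an induced target).
#'
#' @param consensus A [consensus_targets()] result.
#' @param de_mirnas [call_differential()]-style data.frame for miRNAs
#'   (locus_id = miRNA id).
#' @param de_mrnas Likewise for mRNAs (locus_id = gene id).
#' @param require_anticorrelation Keep only pairs whose miRNA and target
#'   directions are opposite (default FALSE).
#' @return data.frame: mirna_id, gene_id, mirna_log2, mirna_direction,
#'   gene_log2, gene_significant, gene_direction; with a `summary`
#'   attribute `c(n_mirnas, n_genes)` over the retained pairs.
#' @export
pair_with_de <- function(consensus, de_mirnas, de_mrnas,
                         require_anticorrelation = FALSE) {
  mid <- normalize_mirna_id(de_mirnas$locus_id)
  sig_mirnas <- de_mirnas[de_mirnas$significant, , drop = FALSE]
  sig_mid <- normalize_mirna_id(sig_mirnas$locus_id)

  keep <- consensus$mirna_id %in% sig_mid
  out <- consensus[keep, c("mirna_id", "gene_id"), drop = FALSE]
  im <- match(out$mirna_id, sig_mid)
  out$mirna_log2 <- sig_mirnas$log2_ratio[im]
  out$mirna_direction <- sig_mirnas$tag_direction[im]
  ig <- match(out$gene_id, de_mrnas$locus_id)
  out$gene_log2 <- de_mrnas$log2_ratio[ig]
  out$gene_significant <- !is.na(ig) & de_mrnas$significant[ig]
  out$gene_direction <- ifelse(out$gene_significant, de_mrnas$tag_direction[ig], "ns")

  if (require_anticorrelation) {
    opp <- (out$mirna_direction == "up" & out$gene_direction == "down") |
           (out$mirna_direction == "down" & out$gene_direction == "up")
    out <- out[opp, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "summary") <- c(n_mirnas = length(unique(out$mirna_id)),
                            n_genes = length(unique(out$gene_id)))
  out
}

#' Read a miRNA-target pair table
#'
#' TSV with columns `mirna_id` and `gene_id`.
#'
#' @param path File path.
#' @return data.frame (mirna_id, gene_id).
#' @export
read_pair_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% names(df))) {
    stop("pair table needs mirna_id and gene_id columns: ", path)
  }
  df[, c("mirna_id", "gene_id")]
}
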