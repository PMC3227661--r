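#' Methylation direction from a tag log2 ratio
#'
#' MMSDK tags report the UNMETHYLATED state of each MluI site, so the
#' methylation direction inverts the tag ratio sign: fewer tags in tumor
#' (log2 <= -1) means hypermethylated, more tags (log2 >= +1) means
#' hypomethylated, otherwise no direction.
#'
#' @param tag_log2 Numeric vector of tag-scale log2 ratios (tumor/normal).
#' @param lfc_threshold Magnitude threshold (default 1, inclusive).
#' @return Character vector: "hypermethylated", "hypomethylated", "none".
#' @export
classify_direction <- function(tag_log2, lfc_threshold = 1) {
  ifelse(tag_log2 <= -lfc_threshold, "hypermethylated",
         ifelse(tag_log2 >= lfc_threshold, "hypomethylated", "none"))
}

#' Join methylation and expression differential results at gene level
#'
#' Methylation records are locus-level; each gene takes its most
#' significant locus (smallest p-value, ties by larger |log2 ratio|, then
#' by locus id).  Genes present in both layers are retained.  The
#' methylation call inverts the tag sign ([classify_direction()]) and
#' requires significance; the joint category pairs it with the expression
#' call: hyper-repressed, hyper-induced, hypo-repressed, hypo-induced, or
#' ns when either layer is not significant.
#'
#' @param meth [call_differential()] result for MMSDK loci.
#' @param expr [call_differential()] result for genes (locus_id = gene).
#' @param annotation [annotate_loci()] result giving locus -> gene_ids.
#' @return data.frame: gene_id, locus_id, meth_log2, meth_fdr, meth_call,
#'   expr_log2, expr_fdr, expr_call, category.  Attribute
#'   `dropped_loci`: number of loci mapping to no gene.
#' @export
join_meth_expr <- function(meth, expr, annotation) {
  ann <- annotation[match(meth$locus_id, annotation$locus_id), ]
  gids <- ifelse(is.na(ann$gene_ids), "", ann$gene_ids)
  genes <- strsplit(gids, ",", fixed = TRUE)
  n_gene <- vapply(genes, function(g) sum(nzchar(g)), integer(1))
  dropped <- sum(n_gene == 0L)

  idx <- rep(seq_len(nrow(meth)), times = vapply(genes, length, integer(1)))
  long <- meth[idx, , drop = FALSE]
  long$gene_id <- unlist(genes, use.names = FALSE)
  long <- long[nzchar(long$gene_id), , drop = FALSE]

  # most significant locus per gene: p asc, |log2| desc, locus_id asc
  o <- order(long$gene_id, long$p_value, -abs(long$log2_ratio), long$locus_id)
  long <- long[o, , drop = FALSE]
  best <- long[!duplicated(long$gene_id), , drop = FALSE]

  ie <- match(best$gene_id, expr$locus_id)
  keep <- !is.na(ie)
  best <- best[keep, , drop = FALSE]
  ie <- ie[keep]

  meth_sig <- best$significant
  meth_call <- ifelse(meth_sig, classify_direction(best$log2_ratio), "ns")
  meth_call[meth_call == "none"] <- "ns"
  expr_sig <- expr$significant[ie]
  expr_call <- ifelse(expr_sig,
                      ifelse(expr$log2_ratio[ie] > 0, "up", "down"), "ns")
  category <- rep("ns", nrow(best))
  both <- meth_call != "ns" & expr_call != "ns"
  category[both] <- paste0(
    ifelse(meth_call[both] == "hypermethylated", "hyper", "hypo"), "-",
    ifelse(expr_call[both] == "up", "induced", "repressed"))

  out <- data.frame(gene_id = best$gene_id, locus_id = best$locus_id,
                    meth_log2 = best$log2_ratio, meth_fdr = best$fdr,
                    meth_call = meth_call, expr_log2 = expr$log2_ratio[ie],
                    expr_fdr = expr$fdr[ie], expr_call = expr_call,
                    category = category, stringsAsFactors = FALSE)
  o2 <- order(out$gene_id)
  out <- out[o2, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_loci") <- dropped
  out
}

#' Right-tail hypergeometric gene-set enrichment
#'
#' For each term with K members in the universe, a query of size n and an
#' overlap of k genes, `p = P(X >= k)` under the hypergeometric law; BH
#' adjustment across all tested terms.  Terms are intersected with the
#' universe before testing; overlap 0 reports p = 1.
#'
#' @param query Character vector of genes, a subset of `universe`.
#' @param universe Character vector of background genes.
#' @param genesets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return data.frame: term_id, term_size, overlap_size, p_value, fdr,
#'   overlapping_gene_ids (comma-separated), sorted by p-value.
#' @export
hypergeom_enrich <- function(query, universe, genesets) {
  query <- unique(query); universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra)) {
    stop("query genes absent from universe: ",
         paste(utils::head(extra, 10L), collapse = ", "))
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(genesets), function(term) {
    members <- intersect(unique(genesets[[term]]), universe)
    K <- length(members)
    ov <- intersect(members, query)
    k <- length(ov)
    p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, term_size = K, overlap_size = k, p_value = p,
               overlapping_gene_ids = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) {
    return(data.frame(term_id = character(0), term_size = integer(0),
                      overlap_size = integer(0), p_value = numeric(0),
                      fdr = numeric(0), overlapping_gene_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id),
             c("term_id", "term_size", "overlap_size", "p_value", "fdr",
               "overlapping_gene_ids")]
  rownames(out) <- NULL
  out
}

#' Export per-locus log2 ratios as a BEDGRAPH-style genome track
#'
#' One file section per layer (methylation, mRNA, miRNA), rows in
#' coordinate order, with the |log2| = 1 significance threshold recorded
#' in the header.
#'
#' @param layers Named list of data.frames with chrom, start, end,
#'   log2_ratio.
#' @param path Output file.
#' @param threshold Significance threshold annotated in the header.
#' @return Invisibly, `path`.
#' @export
export_genome_track <- function(layers, path, threshold = 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# log2(tumor/normal) per locus; significance threshold |log2Ratio| = %g",
                     threshold), con)
  for (layer in names(layers)) {
    df <- layers[[layer]]
    writeLines(sprintf("track type=bedGraph name=\"%s\"", layer), con)
    if (!nrow(df)) next
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%.6g", df$chrom, df$start, df$end,
                       df$log2_ratio), con)
  }
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one tab-separated line per set - name, description, then
#' member genes.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param genesets Named list of character vectors.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(names(genesets), function(nm) {
    paste(c(nm, "na", genesets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
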