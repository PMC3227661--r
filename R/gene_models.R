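#' Gene model container
#'
#' Minimal gene structures for promoter/exon/intron annotation: a gene table
#' and an exon table, 0-based half-open coordinates.  The TSS is the `start`
#' coordinate for "+" genes and `end - 1` for "-" genes.
#'
#' @param genes data.frame with gene_id, chrom, start, end, strand.
#' @param exons data.frame with gene_id, chrom, start, end.
#' @return A `GeneModels` object.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  if (any(genes$end <= genes$start)) stop("gene end must exceed start")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  structure(list(genes = genes, exons = exons), class = "GeneModels")
}

#' @export
print.GeneModels <- function(x, ...) {
  cat(sprintf("GeneModels: %d genes, %d exons\n", nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Write gene models to GFF3
#'
#' @param gm A `GeneModels` object.
#' @param path Output file.
#' @export
write_gene_models_gff3 <- function(gm, path) {
  stopifnot(inherits(gm, "GeneModels"))
  g <- GenomicRanges::GRanges(
    gm$genes$chrom,
    IRanges::IRanges(gm$genes$start + 1L, gm$genes$end),
    strand = gm$genes$strand, type = "gene", ID = gm$genes$gene_id)
  exon_strand <- gm$genes$strand[match(gm$exons$gene_id, gm$genes$gene_id)]
  e <- GenomicRanges::GRanges(
    gm$exons$chrom,
    IRanges::IRanges(gm$exons$start + 1L, gm$exons$end),
    strand = exon_strand, type = "exon", Parent = gm$exons$gene_id)
  rtracklayer::export(c(g, e), path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with `gene` and `exon` features (exons linked by
#'   `Parent`).
#' @return A `GeneModels` object.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  g <- gr[gr$type == "gene"]
  e <- gr[gr$type == "exon"]
  genes <- data.frame(
    gene_id = as.character(g$ID),
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = BiocGenerics::start(g) - 1L, end = BiocGenerics::end(g),
    strand = as.character(BiocGenerics::strand(g)), stringsAsFactors = FALSE)
  parent <- vapply(as.list(e$Parent), function(p) as.character(p)[1], character(1))
  exons <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(e)),
    start = BiocGenerics::start(e) - 1L, end = BiocGenerics::end(e),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}
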