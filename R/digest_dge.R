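#' Build the virtual DGE (NlaIII/CATG) tag reference
#'
#' Emits one entry per CATG occurrence and orientation: on the forward
#' strand the 17 bases immediately 3' of the CATG, and on the reverse
#' strand the reverse complement of the 17 bases immediately 5' of it
#' (which is the sequence 3' of the site on the minus strand).  Entries are
#' annotated with the gene(s) whose body overlaps the tag span; entries
#' overlapping exactly one gene take that gene as their locus, so mapped
#' tags are counted per gene.
#'
#' @param genome Genome as for [find_sites()].
#' @param nla `RestrictionSiteList` for NlaIII (see [nla_sites()]).
#' @param genes Optional [gene_models()] object for gene assignment.
#' @param tag_length Tag length in bases (DGE tags are 17 nt).
#' @return A `VirtualTagLibrary` of kind "DGE" with a `gene_ids` column
#'   (comma-separated; "" when intergenic).
#' @export
build_dge_library <- function(genome, nla, genes = NULL, tag_length = 17L) {
  genome <- as_genome(genome)
  stopifnot(inherits(nla, "RestrictionSiteList"))
  tl <- as.integer(tag_length)

  out <- list()
  for (chrom in names(genome)) {
    seqchr <- as.character(genome[[chrom]])
    L <- nchar(seqchr)
    m <- nla$sites[[chrom]]
    if (length(m) == 0L) next
    site_id <- sprintf("%s:%d", chrom, m)

    f <- which(m + 4L + tl <= L)
    if (length(f)) {
      s0 <- m[f] + 4L
      out[[paste0(chrom, ":F")]] <- data.frame(
        tag_id = paste0(site_id[f], ":F"), site_id = site_id[f],
        chrom = chrom, start = s0, end = s0 + tl, strand = "+",
        side = "downstream",
        tag_17 = substring(seqchr, s0 + 1L, s0 + tl),
        stringsAsFactors = FALSE)
    }
    r <- which(m - tl >= 0L)
    if (length(r)) {
      s0 <- m[r] - tl
      out[[paste0(chrom, ":R")]] <- data.frame(
        tag_id = paste0(site_id[r], ":R"), site_id = site_id[r],
        chrom = chrom, start = s0, end = m[r], strand = "-",
        side = "upstream",
        tag_17 = rev_comp(substring(seqchr, s0 + 1L, m[r])),
        stringsAsFactors = FALSE)
    }
  }

  if (!length(out)) {
    entries <- data.frame(tag_id = character(0), site_id = character(0),
                          chrom = character(0), start = integer(0), end = integer(0),
                          strand = character(0), side = character(0),
                          tag_17 = character(0), gene_ids = character(0),
                          locus_id = character(0), stringsAsFactors = FALSE)
    return(virtual_tag_library(entries, kind = "DGE"))
  }
  entries <- do.call(rbind, c(out, make.row.names = FALSE))

  entries$gene_ids <- ""
  if (!is.null(genes)) {
    stopifnot(inherits(genes, "GeneModels"))
    tag_gr <- GenomicRanges::GRanges(
      entries$chrom, IRanges::IRanges(entries$start + 1L, entries$end))
    gene_gr <- GenomicRanges::GRanges(
      genes$genes$chrom, IRanges::IRanges(genes$genes$start + 1L, genes$genes$end))
    ov <- GenomicRanges::findOverlaps(tag_gr, gene_gr)
    if (length(ov)) {
      hits <- split(genes$genes$gene_id[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov))
      idx <- as.integer(names(hits))
      entries$gene_ids[idx] <- vapply(hits, function(v) paste(sort(unique(v)), collapse = ","),
                                      character(1))
    }
  }
  single_gene <- entries$gene_ids != "" & !grepl(",", entries$gene_ids)
  entries$locus_id <- ifelse(single_gene, entries$gene_ids, entries$site_id)

  virtual_tag_library(entries, kind = "DGE")
}
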