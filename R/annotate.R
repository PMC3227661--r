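#' Annotate tag loci by genic context
#'
#' Assigns each locus exactly one region class with precedence
#' promoter > exon > intron > intergenic.  The promoter is
#' `[TSS - promoter_window, TSS + promoter_window)` (TSS strand-aware); a
#' promoter locus overlapping any CpG island is "CGI-promoter", otherwise
#' "non-CGI-promoter".  `gene_ids` lists every gene whose assigned region
#' (promoter window for promoter loci, gene body otherwise) contains the
#' locus.  MMSDK loci are represented by their MluI recognition site; DGE
#' loci by the span of their tag entries.
#'
#' @param library A `VirtualTagLibrary`.
#' @param genes A [gene_models()] object.
#' @param cgis CpG-island data.frame as from [detect_cgi()] (chrom, start,
#'   end), or NULL for none.
#' @param promoter_window Bases each side of the TSS (default 1000).
#' @return data.frame: locus_id, chrom, start, end, region_class, gene_ids
#'   (comma-separated).
#' @export
annotate_loci <- function(library, genes, cgis = NULL, promoter_window = 1000L) {
  stopifnot(inherits(library, "VirtualTagLibrary"), inherits(genes, "GeneModels"))
  ent <- library$entries

  bad <- setdiff(unique(genes$genes$chrom), unique(ent$chrom))
  if (length(bad)) {
    stop("gene models name chromosome(s) absent from the tag library: ",
         paste(bad, collapse = ", "))
  }

  if (library$kind == "MMSDK") {
    key <- !duplicated(ent$locus_id)
    loci <- data.frame(locus_id = ent$locus_id[key], chrom = ent$chrom[key],
                       start = ent$anchor_site[key],
                       end = ent$anchor_site[key] + 6L, stringsAsFactors = FALSE)
  } else {
    sp <- split(seq_len(nrow(ent)), ent$locus_id)
    loci <- data.frame(
      locus_id = names(sp),
      chrom = vapply(sp, function(i) ent$chrom[i[1]], character(1)),
      start = vapply(sp, function(i) min(ent$start[i]), integer(1)),
      end = vapply(sp, function(i) max(ent$end[i]), integer(1)),
      stringsAsFactors = FALSE)
  }
  rownames(loci) <- NULL

  loc_gr <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$start + 1L, loci$end))
  g <- genes$genes
  w <- as.integer(promoter_window)
  prom_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(g$tss - w, 0L) + 1L, g$tss + w))
  body_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  exon_gr <- GenomicRanges::GRanges(
    genes$exons$chrom, IRanges::IRanges(genes$exons$start + 1L, genes$exons$end))

  ov_collapse <- function(gr, ids) {
    ov <- GenomicRanges::findOverlaps(loc_gr, gr)
    res <- vector("list", length(loc_gr))
    if (length(ov)) {
      sp <- split(ids[S4Vectors::subjectHits(ov)], S4Vectors::queryHits(ov))
      res[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
    }
    res
  }
  prom_hits <- ov_collapse(prom_gr, g$gene_id)
  body_hits <- ov_collapse(body_gr, g$gene_id)
  exon_hits <- ov_collapse(exon_gr, genes$exons$gene_id)

  in_cgi <- rep(FALSE, length(loc_gr))
  if (!is.null(cgis) && nrow(cgis)) {
    cgi_gr <- GenomicRanges::GRanges(cgis$chrom, IRanges::IRanges(cgis$start + 1L, cgis$end))
    in_cgi <- IRanges::overlapsAny(loc_gr, cgi_gr)
  }

  n <- nrow(loci)
  region_class <- character(n)
  gene_ids <- character(n)
  for (i in seq_len(n)) {
    if (!is.null(prom_hits[[i]])) {
      region_class[i] <- if (in_cgi[i]) "CGI-promoter" else "non-CGI-promoter"
      gene_ids[i] <- paste(prom_hits[[i]], collapse = ",")
    } else if (!is.null(exon_hits[[i]])) {
      region_class[i] <- "exon"
      gene_ids[i] <- paste(exon_hits[[i]], collapse = ",")
    } else if (!is.null(body_hits[[i]])) {
      region_class[i] <- "intron"
      gene_ids[i] <- paste(body_hits[[i]], collapse = ",")
    } else {
      region_class[i] <- "intergenic"
      gene_ids[i] <- ""
    }
  }
  loci$region_class <- region_class
  loci$gene_ids <- gene_ids
  loci
}
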