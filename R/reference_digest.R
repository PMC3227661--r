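#' In-silico digestion summary of a reference genome
#'
#' Runs the virtual MluI + NlaIII digestion on a reference genome FASTA
#' (all-unmethylated hypothesis) and reports the bookkeeping used to
#' characterize a tag library: the number of MluI recognition sites, the
#' number of virtual fragments, the number of fragments lacking an
#' internal NlaIII site, and - when a CpG-island track is supplied - the
#' number of MluI loci located inside islands.  For the human hg18
#' assembly with the UCSC cpgIslandExt track these are 21,038 sites,
#' 42,126 fragments, 694 fragments without internal NlaIII, and 2,942
#' loci in islands.
#'
#' @param fasta Path to the genome FASTA.
#' @param cgi_bed Optional BED file of CpG islands (e.g. UCSC
#'   cpgIslandExt); when NULL the island count is NA.
#' @param primary_only Keep only primary assembled chromosomes
#'   (chr1-22, X, Y, M); set FALSE to admit alternates.
#' @return Named list: n_mlu_sites, n_fragments, n_fragments_no_nla,
#'   n_loci_in_cgi.
#' @export
digest_reference_summary <- function(fasta, cgi_bed = NULL, primary_only = TRUE) {
  genome <- read_genome_fasta(fasta)
  if (primary_only) {
    primary <- paste0("chr", c(1:22, "X", "Y", "M"))
    keep <- names(genome) %in% primary
    if (!any(keep)) stop("no primary chromosomes (chr1..chrM) found in ", fasta)
    genome <- genome[keep]
  }
  mlu <- mlu_sites(genome)
  nla <- nla_sites(genome)
  built <- build_mmsdk_library(genome, mlu, nla)

  n_in_cgi <- NA_integer_
  if (!is.null(cgi_bed)) {
    cgi <- read_bed(cgi_bed)
    cgi <- cgi[cgi$chrom %in% names(genome), , drop = FALSE]
    site_df <- do.call(rbind, lapply(names(mlu$sites), function(ch) {
      if (!length(mlu$sites[[ch]])) return(NULL)
      data.frame(chrom = ch, start = mlu$sites[[ch]],
                 end = mlu$sites[[ch]] + 6L, stringsAsFactors = FALSE)
    }))
    sgr <- GenomicRanges::GRanges(site_df$chrom,
                                  IRanges::IRanges(site_df$start + 1L, site_df$end))
    cgr <- GenomicRanges::GRanges(cgi$chrom,
                                  IRanges::IRanges(cgi$start + 1L, cgi$end))
    n_in_cgi <- sum(IRanges::overlapsAny(sgr, cgr))
  }

  list(n_mlu_sites = n_sites(mlu),
       n_fragments = nrow(built$fragments),
       n_fragments_no_nla = sum(!built$fragments$has_internal_nla),
       n_loci_in_cgi = n_in_cgi)
}
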