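#' Simulate a genome with planted restriction cassettes and CpG islands
#'
#' The background is i.i.d. sequence at the configured GC content.  Each
#' planted MluI cassette is `CATG <gap1> ACGCGT <gap2> CATG` with gaps drawn
#' uniformly from 30-500 bases, so every planted MluI site has an NlaIII
#' boundary on both sides and yields both tags.  CpG-island segments are
#' generated CpG-dense and re-drawn until every 200-bp window inside them
#' passes all three island criteria.  Accidental ACGCGT occurrences in the
#' assembled sequence are rewritten until the genome's MluI site set equals
#' the planted set exactly; accidental CATG occurrences are left alone
#' (realistic, and truth tracks MluI anchors only).
#'
#' @param config A [sim_config()] object.
#' @return List with `genome` (named [Biostrings::DNAStringSet]) and
#'   `truth`, a `SimTruth` list: `planted_site_positions` (per-chromosome
#'   0-based ACGCGT starts), `planted_cgi_intervals` (data.frame),
#'   `gene_models` ([gene_models()]), `locus_ids`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(stage_seed(config$seed, "genome"), {
    chrom_len <- distribute_evenly(config$genome_length, config$n_chromosomes)
    chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
    n_mlu <- distribute_evenly(config$n_mlu_sites, config$n_chromosomes)
    n_cgi <- distribute_evenly(config$n_cgis, config$n_chromosomes)
    n_gene <- distribute_evenly(config$n_genes, config$n_chromosomes)

    seqs <- character(config$n_chromosomes)
    site_pos <- stats::setNames(vector("list", config$n_chromosomes), chrom_names)
    cgi_rows <- list()
    gene_rows <- list()
    exon_rows <- list()

    for (ci in seq_len(config$n_chromosomes)) {
      chrom <- chrom_names[ci]
      res <- simulate_chromosome(chrom_len[ci], n_mlu[ci], n_cgi[ci],
                                 config$gc_content, chrom)
      seqs[ci] <- res$seq
      site_pos[[chrom]] <- res$mlu_starts
      if (nrow(res$cgis)) cgi_rows[[chrom]] <- res$cgis

      gm <- place_genes(chrom, chrom_len[ci], n_gene[ci], res$cgis)
      if (nrow(gm$genes)) gene_rows[[chrom]] <- gm$genes
      if (nrow(gm$exons)) exon_rows[[chrom]] <- gm$exons
    }

    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chrom_names
    cgis <- if (length(cgi_rows)) do.call(rbind, c(cgi_rows, make.row.names = FALSE))
            else empty_cgi()[, c("chrom", "start", "end")]
    genes_df <- if (length(gene_rows)) do.call(rbind, c(gene_rows, make.row.names = FALSE))
                else data.frame(gene_id = character(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                strand = character(0), stringsAsFactors = FALSE)
    exons_df <- if (length(exon_rows)) do.call(rbind, c(exon_rows, make.row.names = FALSE))
                else data.frame(gene_id = character(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                stringsAsFactors = FALSE)
    truth <- structure(list(
      planted_site_positions = site_pos,
      planted_cgi_intervals = cgis,
      gene_models = gene_models(genes_df, exons_df),
      locus_ids = unlist(lapply(chrom_names, function(ch)
        sprintf("%s:%d", ch, site_pos[[ch]])), use.names = FALSE)
    ), class = "SimTruth")
    list(genome = genome, truth = truth)
  })
}

distribute_evenly <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

sample_background <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# One CpG-dense segment; re-drawn until every 200-bp window passes the
# three island criteria and it contains no ACGCGT.
sample_cgi_segment <- function(len) {
  for (attempt in 1:100) {
    toks <- sample(c("CG", "A", "C", "G", "T"), size = len,
                   replace = TRUE, prob = c(0.40, 0.21, 0.09, 0.09, 0.21))
    s <- paste(toks, collapse = "")
    s <- substr(s, 1L, len)
    if (nchar(s) < len) next
    if (grepl("ACGCGT", s, fixed = TRUE)) next
    ok <- TRUE
    chk <- detect_cgi_one(s, "seg", 0.5, 0.6, len, min(200L, len), 1L)
    if (nrow(chk) != 1L || chk$start != 0L || chk$end != len) ok <- FALSE
    if (ok) return(s)
  }
  stop("could not generate a CpG-island segment satisfying the criteria")
}

simulate_chromosome <- function(L, n_mlu, n_cgi, gc, chrom) {
  # cassette: CATG gap1 ACGCGT gap2 CATG
  gap1 <- if (n_mlu) sample(30:500, n_mlu, replace = TRUE) else integer(0)
  gap2 <- if (n_mlu) sample(30:500, n_mlu, replace = TRUE) else integer(0)
  cass_span <- gap1 + gap2 + 14L
  cgi_len <- if (n_cgi) sample(250:400, n_cgi, replace = TRUE) else integer(0)

  spans <- c(cass_span, cgi_len)
  types <- c(rep("cassette", n_mlu), rep("cgi", n_cgi))
  n_feat <- length(spans)
  min_gap <- 20L
  if (sum(spans) + (n_feat + 1L) * min_gap > L) {
    stop(sprintf("infeasible packing: %d features need %d bases but chromosome has %d",
                 n_feat, sum(spans) + (n_feat + 1L) * min_gap, L))
  }

  seq_chars <- sample_background(L, gc)
  mlu_starts <- integer(0)
  cgi_df <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                       stringsAsFactors = FALSE)
  cgi_mask <- rep(FALSE, L)

  if (n_feat > 0L) {
    ord <- sample.int(n_feat)
    spans <- spans[ord]; types <- types[ord]
    # original cassette indices in placement order (features 1..n_mlu are cassettes)
    cass_ids <- ord[ord <= n_mlu]
    extra <- L - sum(spans) - (n_feat + 1L) * min_gap
    cuts <- sort(sample.int(extra + 1L, n_feat, replace = TRUE) - 1L)
    starts <- integer(n_feat)
    pos <- min_gap
    for (i in seq_len(n_feat)) {
      pos <- pos + cuts[i] - (if (i > 1L) cuts[i - 1L] else 0L)
      starts[i] <- pos
      pos <- pos + spans[i] + min_gap
    }
    cass_seen <- 0L
    for (i in seq_len(n_feat)) {
      s0 <- starts[i]  # 0-based feature start
      if (types[i] == "cassette") {
        cass_seen <- cass_seen + 1L
        id <- cass_ids[cass_seen]
        a <- gap1[id]; b <- gap2[id]
        seq_chars[(s0 + 1):(s0 + 4)] <- c("C", "A", "T", "G")
        mlu0 <- s0 + 4L + a
        seq_chars[(mlu0 + 1):(mlu0 + 6)] <- c("A", "C", "G", "C", "G", "T")
        catg2 <- mlu0 + 6L + b
        seq_chars[(catg2 + 1):(catg2 + 4)] <- c("C", "A", "T", "G")
        mlu_starts <- c(mlu_starts, mlu0)
      } else {
        len <- spans[i]
        seg <- strsplit(sample_cgi_segment(len), "", fixed = TRUE)[[1]]
        seq_chars[(s0 + 1):(s0 + len)] <- seg
        cgi_mask[(s0 + 1):(s0 + len)] <- TRUE
        cgi_df <- rbind(cgi_df, data.frame(chrom = chrom, start = s0,
                                           end = s0 + len, stringsAsFactors = FALSE))
      }
    }
  }
  mlu_starts <- sort(mlu_starts)

  # scrub accidental ACGCGT to a fixed point, leaving planted sites intact
  s <- paste(seq_chars, collapse = "")
  for (iter in 1:100) {
    occ <- find_motif_starts(s, "ACGCGT")
    accidental <- setdiff(occ, mlu_starts)
    if (!length(accidental)) break
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in accidental) {
      # rewrite the leading 'A' (1-based p + 1); inside an island keep GC up
      ch[p + 1L] <- if (cgi_mask[p + 1L]) "C" else "T"
    }
    s <- paste(ch, collapse = "")
  }
  if (length(setdiff(find_motif_starts(s, "ACGCGT"), mlu_starts))) {
    stop("failed to scrub accidental ACGCGT occurrences")
  }
  if (!all(mlu_starts %in% find_motif_starts(s, "ACGCGT"))) {
    stop("internal error: a planted MluI site was destroyed")
  }
  list(seq = s, mlu_starts = mlu_starts, cgis = cgi_df)
}

# 0-based starts of all (possibly overlapping) occurrences, plain string scan
find_motif_starts <- function(s, motif) {
  out <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(motif, substr(s, from, nchar(s)), fixed = TRUE)
    if (hit < 0) break
    p <- from + as.integer(hit) - 1L
    out <- c(out, p - 1L)
    from <- p + 1L
  }
  out
}

# Genes: half anchored with their TSS inside a planted island (promoter-CGI
# cases), the rest placed uniformly; 2-4 exons per gene.
place_genes <- function(chrom, L, n_gene, cgis) {
  genes <- list(); exons <- list()
  if (n_gene == 0L) {
    return(list(genes = data.frame(gene_id = character(0), chrom = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0), stringsAsFactors = FALSE),
                exons = data.frame(gene_id = character(0), chrom = character(0),
                                   start = integer(0), end = integer(0),
                                   stringsAsFactors = FALSE)))
  }
  n_at_cgi <- min(nrow(cgis), n_gene %/% 2L)
  cgi_pick <- if (n_at_cgi) sample.int(nrow(cgis), n_at_cgi) else integer(0)
  for (gi in seq_len(n_gene)) {
    len <- sample(2000:6000, 1L)
    if (gi <= n_at_cgi) {
      tss <- cgis$start[cgi_pick[gi]] + sample(10:100, 1L)
      strand <- "+"
      start <- tss
      end <- min(tss + len, L)
    } else {
      strand <- sample(c("+", "-"), 1L)
      start <- sample.int(max(L - len, 1L), 1L) - 1L
      end <- min(start + len, L)
    }
    if (end - start < 400L) next
    id <- sprintf("%s_g%03d", chrom, gi)
    genes[[gi]] <- data.frame(gene_id = id, chrom = chrom, start = start,
                              end = end, strand = strand, stringsAsFactors = FALSE)
    n_ex <- sample(2:4, 1L)
    bounds <- sort(sample(seq(start + 50L, end - 50L, by = 10L), 2L * n_ex))
    exons[[gi]] <- data.frame(gene_id = id, chrom = chrom,
                              start = bounds[seq(1L, 2L * n_ex, by = 2L)],
                              end = bounds[seq(2L, 2L * n_ex, by = 2L)],
                              stringsAsFactors = FALSE)
  }
  list(genes = do.call(rbind, c(genes, make.row.names = FALSE)),
       exons = do.call(rbind, c(exons, make.row.names = FALSE)))
}
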