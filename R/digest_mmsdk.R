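#' Build the virtual MMSDK fragment and tag library
#'
#' Simulates the MluI + NlaIII double digest under the all-unmethylated
#' hypothesis.  Each MluI cut (A^CGCGT) releases an upstream and a
#' downstream fragment that extend to the nearest NlaIII cut (CATG^) or, if
#' one intervenes first, to an obstacle: the chromosome end or the adjacent
#' MluI cut.  Fragments whose NlaIII-side boundary is an obstacle carry no
#' internal NlaIII site and yield no tag.  Otherwise the tag is the 17/18
#' bases of the fragment immediately interior to the NlaIII cut (CATG
#' excluded), read from the boundary into the fragment, which for the
#' downstream fragment means the reverse complement of the forward strand.
#' Fragments with fewer than 18 bases past the CATG yield no tag.
#'
#' All coordinates are 0-based, half-open.
#'
#' @param genome Genome as for [find_sites()].
#' @param mlu `RestrictionSiteList` for MluI (see [mlu_sites()]).
#' @param nla `RestrictionSiteList` for NlaIII (see [nla_sites()]).
#' @param tag_lengths Tag lengths emitted (fixed 17/18 design).
#' @return List with `fragments` (data.frame: chrom, start, end,
#'   anchor_site, side, boundary, boundary_type, has_internal_nla) and
#'   `library`, a `VirtualTagLibrary` of kind "MMSDK" (one locus per MluI
#'   site, at most two tag entries per locus).
#' @export
build_mmsdk_library <- function(genome, mlu, nla, tag_lengths = c(17L, 18L)) {
  genome <- as_genome(genome)
  stopifnot(inherits(mlu, "RestrictionSiteList"), inherits(nla, "RestrictionSiteList"))
  if (!identical(sort(names(mlu$sites)), sort(names(genome))) ||
      !identical(sort(names(nla$sites)), sort(names(genome)))) {
    stop("site lists and genome name different chromosome sets")
  }
  tmax <- max(tag_lengths)

  frag_list <- list()
  tag_list <- list()
  for (chrom in names(genome)) {
    seqchr <- as.character(genome[[chrom]])
    L <- nchar(seqchr)
    m_starts <- mlu$sites[[chrom]]
    if (length(m_starts) == 0L) next
    cuts_m <- m_starts + mlu$cut_offset
    cuts_n <- nla$sites[[chrom]] + nla$cut_offset

    n_m <- length(cuts_m)
    # nearest NlaIII cut strictly left / right of each MluI cut
    idx_left <- findInterval(cuts_m - 0.5, cuts_n)
    left_n <- ifelse(idx_left > 0, cuts_n[pmax(idx_left, 1L)], -Inf)
    idx_right <- findInterval(cuts_m + 0.5, cuts_n)
    right_n <- ifelse(idx_right < length(cuts_n), cuts_n[pmin(idx_right + 1L, length(cuts_n))], Inf)
    prev_m <- c(-Inf, cuts_m[-n_m])
    next_m <- c(cuts_m[-1L], Inf)

    up_b <- pmax(0, prev_m, left_n)
    up_type <- ifelse(is.finite(left_n) & left_n == up_b, "nla",
                      ifelse(is.finite(prev_m) & prev_m == up_b, "mlu", "chrom_start"))
    dn_e <- pmin(L, next_m, right_n)
    dn_type <- ifelse(is.finite(right_n) & right_n == dn_e, "nla",
                      ifelse(is.finite(next_m) & next_m == dn_e, "mlu", "chrom_end"))

    locus_id <- sprintf("%s:%d", chrom, m_starts)

    up_keep <- up_b < cuts_m
    dn_keep <- cuts_m < dn_e
    fr <- rbind(
      data.frame(chrom = chrom, start = as.integer(up_b[up_keep]),
                 end = as.integer(cuts_m[up_keep]),
                 anchor_site = m_starts[up_keep], locus_id = locus_id[up_keep],
                 side = "upstream", boundary = as.integer(up_b[up_keep]),
                 boundary_type = up_type[up_keep],
                 has_internal_nla = up_type[up_keep] == "nla",
                 stringsAsFactors = FALSE),
      data.frame(chrom = chrom, start = as.integer(cuts_m[dn_keep]),
                 end = as.integer(dn_e[dn_keep]),
                 anchor_site = m_starts[dn_keep], locus_id = locus_id[dn_keep],
                 side = "downstream", boundary = as.integer(dn_e[dn_keep]),
                 boundary_type = dn_type[dn_keep],
                 has_internal_nla = dn_type[dn_keep] == "nla",
                 stringsAsFactors = FALSE)
    )
    frag_list[[chrom]] <- fr

    # upstream tags: forward strand from the NlaIII cut into the fragment
    u <- which(up_type == "nla" & (cuts_m - up_b) >= tmax)
    if (length(u)) {
      b <- as.integer(up_b[u])
      tag18 <- substring(seqchr, b + 1L, b + tmax)
      tag_list[[paste0(chrom, ":U")]] <- data.frame(
        tag_id = paste0(locus_id[u], ":upstream"), locus_id = locus_id[u],
        chrom = chrom, start = b, end = b + tmax, strand = "+",
        side = "upstream", anchor_site = m_starts[u],
        tag_17 = substring(tag18, 1L, min(tag_lengths)), tag_18 = tag18,
        stringsAsFactors = FALSE)
    }
    # downstream tags: read from the NlaIII cut back into the fragment
    # (minus strand); CATG occupies [e-4, e)
    d <- which(dn_type == "nla" & (dn_e - 4 - cuts_m) >= tmax)
    if (length(d)) {
      e <- as.integer(dn_e[d])
      fwd18 <- substring(seqchr, e - 4L - tmax + 1L, e - 4L)
      tag18 <- rev_comp(fwd18)
      tag_list[[paste0(chrom, ":D")]] <- data.frame(
        tag_id = paste0(locus_id[d], ":downstream"), locus_id = locus_id[d],
        chrom = chrom, start = e - 4L - tmax, end = e - 4L, strand = "-",
        side = "downstream", anchor_site = m_starts[d],
        tag_17 = substring(tag18, 1L, min(tag_lengths)), tag_18 = tag18,
        stringsAsFactors = FALSE)
    }
  }

  fragments <- if (length(frag_list)) do.call(rbind, c(frag_list, make.row.names = FALSE))
               else empty_fragments()
  entries <- if (length(tag_list)) do.call(rbind, c(tag_list, make.row.names = FALSE))
             else empty_mmsdk_entries()
  # all loci, including tag-less ones, are part of the locus universe
  loci <- unique(fragments$locus_id)
  list(fragments = fragments,
       library = virtual_tag_library(entries, kind = "MMSDK", loci = loci))
}

empty_fragments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             anchor_site = integer(0), locus_id = character(0), side = character(0),
             boundary = integer(0), boundary_type = character(0),
             has_internal_nla = logical(0), stringsAsFactors = FALSE)
}

empty_mmsdk_entries <- function() {
  data.frame(tag_id = character(0), locus_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             side = character(0), anchor_site = integer(0),
             tag_17 = character(0), tag_18 = character(0), stringsAsFactors = FALSE)
}

#' Virtual tag library container
#'
#' @param entries data.frame of tag entries (tag_id, locus_id, chrom, start,
#'   end, strand, side, tag_17 and/or tag_18, optional gene_ids).
#' @param kind "MMSDK" or "DGE".
#' @param loci Full locus universe (defaults to loci present in `entries`).
#' @return A `VirtualTagLibrary`.
#' @export
virtual_tag_library <- function(entries, kind = c("MMSDK", "DGE"), loci = NULL) {
  kind <- match.arg(kind)
  if (is.null(loci)) loci <- unique(entries$locus_id)
  structure(list(kind = kind, entries = entries, loci = loci),
            class = "VirtualTagLibrary")
}

#' @export
print.VirtualTagLibrary <- function(x, ...) {
  cat(sprintf("VirtualTagLibrary (%s): %d tag entries over %d loci\n",
              x$kind, nrow(x$entries), length(x$loci)))
  invisible(x)
}
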