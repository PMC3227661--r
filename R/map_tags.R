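#' Map tags to a virtual library with at most one mismatch
#'
#' A tag is assigned to a locus iff it has exactly one library entry at its
#' minimal Hamming distance and that distance is at most `max_mismatch`;
#' tags with two or more best hits are discarded as ambiguous (never
#' rescued), and matching is orientation-aware: the tag or its reverse
#' complement may match, both counting as the same entry.  Reads of 18
#' bases are matched against the 18-mer forms first and fall back to their
#' 17-mer prefix; both resolve to the same library entry.
#'
#' @param tags A [read_set()] or character vector of tag sequences.
#' @param library A `VirtualTagLibrary`.
#' @param max_mismatch Maximum Hamming distance (default 1).
#' @return data.frame: seq, count, status ("mapped", "ambiguous",
#'   "unmapped"), locus_id, tag_id, distance.  Conservation holds:
#'   mapped + ambiguous + unmapped = input reads.
#' @export
map_tags <- function(tags, library, max_mismatch = 1L) {
  stopifnot(inherits(library, "VirtualTagLibrary"))
  if (inherits(tags, "ReadSet")) {
    df <- tags$reads[, c("seq", "count")]
  } else {
    tab <- table(tags)
    df <- data.frame(seq = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  }
  ent <- library$entries
  if (!nrow(ent)) {
    if (nrow(df)) warning("empty tag library: all tags unmapped")
    df$status <- rep("unmapped", nrow(df))
    df$locus_id <- NA_character_; df$tag_id <- NA_character_
    df$distance <- NA_integer_
    return(df)
  }

  idx18 <- build_tag_index(ent, "tag_18")
  idx17 <- build_tag_index(ent, "tag_17")

  n <- nrow(df)
  status <- character(n); locus <- rep(NA_character_, n)
  tagid <- rep(NA_character_, n); dist <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    q <- df$seq[i]
    hit <- NULL
    if (nchar(q) >= 18L && !is.null(idx18)) {
      hit <- lookup_tag(substr(q, 1L, 18L), idx18, max_mismatch)
    }
    if ((is.null(hit) || hit$n == 0L) && nchar(q) >= 17L && !is.null(idx17)) {
      hit <- lookup_tag(substr(q, 1L, 17L), idx17, max_mismatch)
    }
    if (is.null(hit) || hit$n == 0L) {
      status[i] <- "unmapped"
    } else if (hit$n > 1L) {
      status[i] <- "ambiguous"
    } else {
      status[i] <- "mapped"
      locus[i] <- ent$locus_id[hit$entry]
      tagid[i] <- ent$tag_id[hit$entry]
      dist[i] <- hit$distance
    }
  }
  df$status <- status; df$locus_id <- locus; df$tag_id <- tagid
  df$distance <- dist
  rownames(df) <- NULL
  df
}

# Hash both orientations of one tag-length column to entry row indices.
build_tag_index <- function(ent, col) {
  if (is.null(ent[[col]])) return(NULL)
  seqs <- ent[[col]]
  ok <- !is.na(seqs) & nzchar(seqs)
  if (!any(ok)) return(NULL)
  rows <- which(ok)
  keys <- c(seqs[ok], rev_comp(seqs[ok]))
  entry <- c(rows, rows)
  env <- new.env(hash = TRUE, parent = emptyenv(), size = 2L * length(rows))
  for (k in seq_along(keys)) {
    cur <- env[[keys[k]]]
    env[[keys[k]]] <- if (is.null(cur)) entry[k] else unique(c(cur, entry[k]))
  }
  list(env = env, len = nchar(seqs[rows[1L]]))
}

# Entries at minimal distance (0 preferred, then 1); n = count of distinct
# entries at that distance.
lookup_tag <- function(q, idx, max_mismatch) {
  if (nchar(q) != idx$len) return(list(n = 0L))
  exact <- idx$env[[q]]
  if (!is.null(exact)) {
    ents <- unique(exact)
    return(list(n = length(ents), entry = ents[1L], distance = 0L))
  }
  if (max_mismatch < 1L) return(list(n = 0L))
  ents <- integer(0)
  bases <- c("A", "C", "G", "T")
  for (p in seq_len(idx$len)) {
    orig <- substr(q, p, p)
    for (b in bases) {
      if (b == orig) next
      v <- q
      substr(v, p, p) <- b
      hit <- idx$env[[v]]
      if (!is.null(hit)) ents <- c(ents, hit)
    }
  }
  ents <- unique(ents)
  if (!length(ents)) return(list(n = 0L))
  list(n = length(ents), entry = ents[1L], distance = 1L)
}

#' Count uniquely mapped tags per locus
#'
#' Sums mapped-tag multiplicities per locus (for MMSDK both tag entries of
#' an MluI locus pool into that locus; for DGE entries pool per gene) and
#' records the per-sample mapped totals as library sizes.  Loci without
#' reads are retained with count zero.
#'
#' @param assignments Named list of [map_tags()] results, one per sample.
#' @param library The `VirtualTagLibrary` mapped against (fixes the locus
#'   universe).
#' @param conditions Condition labels per sample.
#' @return A [tag_count_matrix()].
#' @export
count_per_locus <- function(assignments, library, conditions) {
  stopifnot(inherits(library, "VirtualTagLibrary"))
  loci <- library$loci
  m <- matrix(0L, nrow = length(loci), ncol = length(assignments),
              dimnames = list(loci, names(assignments)))
  for (j in seq_along(assignments)) {
    a <- assignments[[j]]
    a <- a[a$status == "mapped", , drop = FALSE]
    if (!nrow(a)) next
    agg <- tapply(a$count, a$locus_id, sum)
    m[names(agg), j] <- as.integer(agg)
  }
  tag_count_matrix(m, conditions)
}
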