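#' Clip a 3' adapter by semi-global dynamic programming
#'
#' The adapter is aligned against every suffix of the read: both sequences
#' are anchored at the suffix start, the read suffix must be fully
#' consumed, and the adapter's right end is free (it may run past the read
#' end).  Scoring is +1 match, -1 mismatch, -2 gap.  If the best suffix
#' scores at least `min_score` the read is truncated at that suffix start;
#' otherwise it is returned unchanged.  An empty adapter is a no-op;
#' adapters of 1-5 bases are rejected as unclippable.
#'
#' @param reads Character vector of read sequences.
#' @param adapter Adapter sequence.
#' @param match,mismatch,gap Alignment scores.
#' @param min_score Minimum alignment score to clip.
#' @return Character vector of clipped reads.
#' @export
clip_adapter <- function(reads, adapter, match = 1, mismatch = -1, gap = -2,
                         min_score = 7) {
  if (!nzchar(adapter)) return(reads)
  if (nchar(adapter) < 6L) stop("adapter must be at least 6 bases")
  out <- reads
  nonempty <- which(nzchar(reads))

  # fast path: adapter occurs verbatim and runs to the read end (possibly
  # truncated); full DP only for the rest
  full <- regexpr(adapter, out[nonempty], fixed = TRUE)
  fast <- integer(0)
  if (length(nonempty)) {
    cand <- which(full > 0)
    for (i in cand) {
      idx <- nonempty[i]
      pos <- as.integer(full[i])
      tail_len <- nchar(out[idx]) - pos + 1L
      sc <- min(tail_len, nchar(adapter)) * match
      if (tail_len <= nchar(adapter) && sc >= min_score) {
        out[idx] <- substr(out[idx], 1L, pos - 1L)
        fast <- c(fast, idx)
      }
    }
  }
  slow <- setdiff(nonempty, fast)
  for (idx in slow) {
    cut <- clip_position(out[idx], adapter, match, mismatch, gap, min_score)
    if (!is.na(cut)) out[idx] <- substr(out[idx], 1L, cut - 1L)
  }
  out
}

# Best clip position (1-based suffix start) or NA.  Scores every suffix
# start with a small DP; ties resolved toward the leftmost (longest
# adapter) suffix with the maximal score.
clip_position <- function(read, adapter, match, mismatch, gap, min_score) {
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  n <- length(r); m <- length(a)
  best_score <- -Inf
  best_i <- NA_integer_
  for (i in seq_len(n)) {
    s <- r[i:n]
    ls <- n - i + 1L
    # F[p+1, q+1]: first p bases of suffix vs first q of adapter
    prev <- c(0, seq_len(m) * gap)
    for (p in seq_len(ls)) {
      cur <- numeric(m + 1L)
      cur[1L] <- p * gap
      for (q in seq_len(m)) {
        d <- prev[q] + if (s[p] == a[q]) match else mismatch
        cur[q + 1L] <- max(d, prev[q + 1L] + gap, cur[q] + gap)
      }
      prev <- cur
    }
    sc <- max(prev)  # adapter right end free
    if (sc > best_score) {
      best_score <- sc
      best_i <- i
    }
  }
  if (is.finite(best_score) && best_score >= min_score) best_i else NA_integer_
}

#' @rdname clip_adapter
#' @param rs A [read_set()]; every sequence is clipped and the multiset
#'   re-collapsed.
#' @export
clip_read_set <- function(rs, adapter, match = 1, mismatch = -1, gap = -2,
                          min_score = 7) {
  stopifnot(inherits(rs, "ReadSet"))
  clipped <- clip_adapter(rs$reads$seq, adapter, match, mismatch, gap, min_score)
  read_set(rep(clipped, rs$reads$count), sample_id = rs$sample_id,
           condition = rs$condition)
}
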