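#' Detect CpG islands by the three classic criteria
#'
#' A sliding seed-and-merge caller: every `window`-bp window (stepped by
#' `step`) that satisfies GC fraction >= `min_gc` and observed/expected CpG
#' ratio > `min_obs_exp` is a seed; overlapping seeds are merged; merged
#' regions are re-tested on their full span and trimmed one base at a time
#' (alternating ends) until the span itself satisfies all criteria; regions
#' shorter than `min_len` (strictly more than 200 bp under the defaults)
#' are dropped.  The observed/expected ratio is
#' `n_CpG * L / (n_C * n_G)`.
#'
#' @param genome Genome as for [find_sites()].
#' @param min_gc Minimum GC fraction (default 0.5, inclusive).
#' @param min_obs_exp Minimum obs/exp CpG ratio (default 0.6, exclusive).
#' @param min_len Minimum region length in bases (default 201, i.e. > 200).
#' @param window Seed window size in bases.
#' @param step Seed window step in bases.
#' @return data.frame: chrom, start, end (0-based half-open), gc_fraction,
#'   obs_exp_cpg.
#' @export
detect_cgi <- function(genome, min_gc = 0.5, min_obs_exp = 0.6, min_len = 201L,
                       window = 200L, step = 1L) {
  genome <- as_genome(genome)
  out <- lapply(names(genome), function(chrom) {
    detect_cgi_one(as.character(genome[[chrom]]), chrom, min_gc, min_obs_exp,
                   min_len, window, step)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  if (is.null(res)) res <- empty_cgi()
  res
}

empty_cgi <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             gc_fraction = numeric(0), obs_exp_cpg = numeric(0),
             stringsAsFactors = FALSE)
}

detect_cgi_one <- function(seqchr, chrom, min_gc, min_obs_exp, min_len, window, step) {
  L <- nchar(seqchr)
  if (L < window) return(empty_cgi())
  b <- strsplit(seqchr, "", fixed = TRUE)[[1]]
  is_c <- b == "C"
  is_g <- b == "G"
  # CpG dinucleotide starting at i (1-based), length L-1
  is_cpg <- c(is_c[-L] & is_g[-1L], FALSE)
  cum_c <- c(0, cumsum(is_c))
  cum_g <- c(0, cumsum(is_g))
  cum_cpg <- c(0, cumsum(is_cpg))

  # window stats; a CpG counts when fully inside the window
  starts <- seq.int(1L, L - window + 1L, by = step)  # 1-based window starts
  nc <- cum_c[starts + window] - cum_c[starts]
  ng <- cum_g[starts + window] - cum_g[starts]
  ncpg <- cum_cpg[starts + window - 1L] - cum_cpg[starts]
  gc <- (nc + ng) / window
  oe <- ifelse(nc * ng > 0, ncpg * window / (nc * ng), 0)
  pass <- gc >= min_gc & oe > min_obs_exp

  if (!any(pass)) return(empty_cgi())
  r <- rle(pass)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- which(r$values)

  span_stats <- function(s, e) {  # 1-based inclusive span
    len <- e - s + 1L
    nc <- cum_c[e + 1L] - cum_c[s]
    ng <- cum_g[e + 1L] - cum_g[s]
    ncpg <- cum_cpg[e] - cum_cpg[s]
    gc <- (nc + ng) / len
    oe <- if (nc * ng > 0) ncpg * len / (nc * ng) else 0
    c(gc = gc, oe = oe)
  }

  rows <- list()
  for (k in keep) {
    s <- starts[idx_start[k]]
    e <- starts[idx_end[k]] + window - 1L
    # trim alternating ends until the full span passes all criteria
    trim_right <- TRUE
    repeat {
      if (e - s + 1L < min_len) break
      st <- span_stats(s, e)
      if (st["gc"] >= min_gc && st["oe"] > min_obs_exp) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = s - 1L, end = e,
          gc_fraction = unname(st["gc"]), obs_exp_cpg = unname(st["oe"]),
          stringsAsFactors = FALSE)
        break
      }
      if (trim_right) e <- e - 1L else s <- s + 1L
      trim_right <- !trim_right
    }
  }
  if (!length(rows)) return(empty_cgi())
  do.call(rbind, c(rows, make.row.names = FALSE))
}
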