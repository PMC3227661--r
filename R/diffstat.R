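#' Tags-per-million normalization
#'
#' @param count Tag count(s).
#' @param library_size Total high-quality tags in the library (> 0).
#' @return `count / library_size * 1e6`.
#' @export
normalize_tpm <- function(count, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / library_size * 1e6
}

#' Audic-Claverie test for a tag count in two libraries
#'
#' Given `x` tags at a locus in a library of `n1` total tags and `y` tags
#' in a library of `n2` tags, the conditional probability of observing `k`
#' tags in the second library is
#' `p(k|x) = r^k (x+k)! / (x! k! (1+r)^(x+k+1))` with `r = n2/n1`.  The
#' two-sided p-value doubles the smaller of the two inclusive tails at the
#' observed `y` and caps at 1:
#' `p = min(1, 2 min(sum_{k<=y} p(k|x), sum_{k>=y} p(k|x)))`.
#' Both tails are summed directly in log space (no complementation), so
#' the result matches direct summation to well below 1e-12.  With
#' `alternative = "less_likely"` the alternative convention - the total
#' mass of outcomes no more probable than the observed one - is used.
#'
#' @param x,y Integer tag counts (pooled counts must be rounded first).
#' @param n1,n2 Library sizes (> 0).
#' @param alternative "two_sided" (tail doubling, default) or
#'   "less_likely".
#' @return p-value in `[0, 1]`.
#' @export
ac_pvalue <- function(x, y, n1, n2, alternative = c("two_sided", "less_likely")) {
  alternative <- match.arg(alternative)
  if (length(x) > 1L || length(y) > 1L) {
    return(mapply(ac_pvalue, x, y, MoreArgs = list(n1 = n1, n2 = n2,
                                                   alternative = alternative)))
  }
  if (x != round(x) || y != round(y)) {
    stop("counts must be integers; round pooled counts first")
  }
  if (x < 0 || y < 0) stop("counts must be non-negative")
  if (n1 <= 0 || n2 <= 0) stop("library sizes must be positive")
  r <- n2 / n1
  lmass <- function(k) k * log(r) + lchoose(x + k, k) - (x + k + 1) * log1p(r)

  # lower tail: k = 0..y
  lower <- sum(exp(lmass(0:y)))
  # upper tail: k = y..K, summed until the residual is negligible
  upper <- ac_upper_tail(lmass, y, x, r)
  p <- switch(alternative,
    two_sided = 2 * min(lower, upper),
    less_likely = {
      lobs <- lmass(y)
      kmax <- ac_kmax(y, x, r)
      lm <- lmass(0:kmax)
      sum(exp(lm[lm <= lobs + 1e-12]))
    })
  min(1, p)
}

# direct log-space summation of the upper tail from k = y upward
ac_upper_tail <- function(lmass, y, x, r) {
  kmax <- ac_kmax(y, x, r)
  sum(exp(lmass(y:kmax)))
}

# index beyond which the negative-binomial mass is numerically negligible
ac_kmax <- function(y, x, r) {
  mu <- (x + 1) * r            # mean of the conditional distribution
  sdv <- sqrt((x + 1) * r * (1 + r))
  max(y + 50L, ceiling(mu + 20 * sdv + 50))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorts the m p-values ascending, takes
#' `adj_(i) = min_{j >= i} (p_(j) m / j)` capped at 1, and returns the
#' adjusted values in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (FDR) in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Differential tag-abundance calls for pooled tumor/normal libraries
#'
#' For each locus, normalizes the pooled counts to TPM, computes
#' `log2_ratio = log2((tpm_tumor + pseudo) / (tpm_normal + pseudo))`, the
#' Audic-Claverie p-value on the raw integer counts, the BH FDR across the
#' supplied loci, and the significance call
#' `fdr <= fdr_threshold & |log2_ratio| >= lfc_threshold` (inclusive,
#' defaults FDR 0.05 and |log2| 1).
#'
#' @param pairs data.frame with columns locus_id, x (tumor count), y
#'   (normal count), n1, n2 (library sizes), e.g. from [pool_by_mean()] of
#'   both conditions.
#' @param lfc_threshold Minimum |log2 ratio| (default 1).
#' @param fdr_threshold Maximum FDR (default 0.05).
#' @param pseudo Pseudocount in TPM units for the ratio only (default
#'   0.5); p-values always use the raw integer counts.
#' @return data.frame: locus_id, x, y, n1, n2, tpm_tumor, tpm_normal,
#'   log2_ratio, p_value, fdr, significant, tag_direction ("up", "down",
#'   "none").
#' @export
call_differential <- function(pairs, lfc_threshold = 1, fdr_threshold = 0.05,
                              pseudo = 0.5) {
  req <- c("locus_id", "x", "y", "n1", "n2")
  if (!all(req %in% names(pairs))) {
    stop("pairs needs columns: ", paste(req, collapse = ", "))
  }
  tpm_t <- normalize_tpm(pairs$x, pairs$n1)
  tpm_n <- normalize_tpm(pairs$y, pairs$n2)
  l2r <- log2((tpm_t + pseudo) / (tpm_n + pseudo))
  pv <- mapply(ac_pvalue, pairs$x, pairs$y, pairs$n1, pairs$n2)
  fdr <- bh_adjust(pv)
  sig <- fdr <= fdr_threshold & abs(l2r) >= lfc_threshold
  dir <- ifelse(l2r > 0, "up", ifelse(l2r < 0, "down", "none"))
  data.frame(locus_id = pairs$locus_id, x = pairs$x, y = pairs$y,
             n1 = pairs$n1, n2 = pairs$n2, tpm_tumor = tpm_t,
             tpm_normal = tpm_n, log2_ratio = l2r, p_value = pv, fdr = fdr,
             significant = sig, tag_direction = dir, stringsAsFactors = FALSE)
}

#' Assemble the pooled two-library table from a count matrix
#'
#' Convenience wrapper: pools tumor and normal libraries by mean
#' ([pool_by_mean()]) and lays them out for [call_differential()].
#'
#' @param tcm A [tag_count_matrix()].
#' @return data.frame with locus_id, x, y, n1, n2.
#' @export
pooled_pairs <- function(tcm) {
  t_ <- pool_by_mean(tcm, "tumor")
  n_ <- pool_by_mean(tcm, "normal")
  data.frame(locus_id = names(t_$counts), x = unname(t_$counts),
             y = unname(n_$counts), n1 = t_$library_size, n2 = n_$library_size,
             stringsAsFactors = FALSE)
}

#' Compare tumor-vs-normal log2 distributions per genomic region class
#'
#' Two-sided Wilcoxon rank-sum per region class (CpG-rich promoters,
#' CpG-poor promoters, exons, introns, ...): exact enumeration when both
#' groups have at most 12 untied observations, otherwise the normal
#' approximation with tie correction and continuity correction.
#' Degenerate all-tied input yields p = 1 with a warning.
#'
#' @param values Numeric vector of region-wise log2 summaries.
#' @param region_class Region class per value.
#' @param group Group label per value (exactly two levels, e.g.
#'   tumor/normal).
#' @return data.frame: region_class, n1, n2, p_value.
#' @export
compare_region_distributions <- function(values, region_class, group) {
  stopifnot(length(values) == length(region_class),
            length(values) == length(group))
  lv <- unique(group)
  if (length(lv) != 2L) stop("group must have exactly two levels")
  out <- lapply(split(seq_along(values), region_class), function(idx) {
    a <- values[idx][group[idx] == lv[1]]
    b <- values[idx][group[idx] == lv[2]]
    if (length(a) < 2L || length(b) < 2L) {
      stop("each region class needs at least 2 observations per group")
    }
    p <- if (length(unique(c(a, b))) == 1L) {
      warning("all observations tied in a region class; p = 1")
      1
    } else {
      ties <- any(duplicated(c(a, b)))
      exact <- length(a) <= 12L && length(b) <= 12L && !ties
      suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                          exact = exact, correct = TRUE)$p.value)
    }
    data.frame(n1 = length(a), n2 = length(b), p_value = p)
  })
  res <- do.call(rbind, out)
  data.frame(region_class = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}
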