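# Independent brute-force oracles and small fixture builders shared by the
# suite.  Oracles are deliberately naive re-derivations of each contract,
# kept free of the implementation's code paths.

random_dna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# every occurrence (0-based starts) by direct position-by-position comparison
naive_scan <- function(s, motif) {
  L <- nchar(s); m <- nchar(motif)
  if (L < m) return(integer(0))
  starts <- 1:(L - m + 1L)
  which(substring(s, starts, starts + m - 1L) == motif) - 1L
}

hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

# two-sided Audic-Claverie by direct summation with 1e-15 tail truncation
ac_oracle <- function(x, y, n1, n2) {
  r <- n2 / n1
  lp <- function(k) k * log(r) + lchoose(x + k, k) - (x + k + 1) * log1p(r)
  lower <- sum(exp(lp(0:y)))
  upper <- 0; k <- y
  kmin <- (x + 1) * r + 10 * sqrt((x + 1) * r * (1 + r)) + y
  repeat {
    t <- exp(lp(k)); upper <- upper + t; k <- k + 1
    if (t < 1e-15 && k > kmin) break
  }
  min(1, 2 * min(lower, upper))
}

# textbook step-up: sort ascending, adj_(i) = min_{j>=i} p_(j) m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

hyper_oracle <- function(k, K, N, n) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i) / choose(N, n))
}

# naive MluI/NlaIII double-digest: per MluI cut walk left and right to the
# nearest NlaIII cut or obstacle; emit fragments and 18-nt tags
brute_digest <- function(s) {
  mlu <- naive_scan(s, "ACGCGT"); nla <- naive_scan(s, "CATG")
  cuts_m <- mlu + 1L; cuts_n <- nla + 4L; L <- nchar(s)
  frags <- list(); tags <- list()
  for (i in seq_along(cuts_m)) {
    c0 <- cuts_m[i]
    lefts <- c(0L, cuts_m[cuts_m < c0], cuts_n[cuts_n < c0])
    b <- max(lefts)
    up_nla <- b %in% cuts_n
    if (b < c0) frags[[length(frags) + 1L]] <- c(b, c0, up_nla)
    if (up_nla && (c0 - b) >= 18L) {
      tags[[length(tags) + 1L]] <- list(locus = mlu[i], side = "up",
                                        seq = substr(s, b + 1L, b + 18L))
    }
    rights <- c(L, cuts_m[cuts_m > c0], cuts_n[cuts_n > c0])
    e <- min(rights)
    dn_nla <- e %in% cuts_n
    if (c0 < e) frags[[length(frags) + 1L]] <- c(c0, e, dn_nla)
    if (dn_nla && (e - 4L - c0) >= 18L) {
      fwd <- substr(s, e - 21L, e - 4L)
      tags[[length(tags) + 1L]] <- list(locus = mlu[i], side = "down",
                                        seq = rev_comp(fwd))
    }
  }
  list(sites = mlu,
       fragments = if (length(frags)) do.call(rbind, frags) else matrix(0, 0, 3),
       tags = tags)
}

# consensus by naive set algebra on pair strings
consensus_oracle <- function(pred, exper, min_pred = 2L) {
  keyize <- function(df) unique(paste(sub("^hsa-", "", tolower(df$mirna_id)),
                                      df$gene_id, sep = "|"))
  pk <- lapply(pred, keyize)
  all_keys <- unique(unlist(pk))
  n_src <- vapply(all_keys, function(k) sum(vapply(pk, function(v) k %in% v, logical(1))),
                  integer(1))
  a <- all_keys[n_src >= min_pred]
  b <- unique(unlist(lapply(exper, keyize)))
  sort(intersect(a, b))
}

# small MMSDK-style library with known tag sequences, for mapper tests
toy_tag_library <- function(n = 200L, seed = 11L, len = 18L) {
  set.seed(seed)
  seqs <- unique(replicate(n, random_dna(len, 0.5)))
  ent <- data.frame(
    tag_id = paste0("t", seq_along(seqs)),
    locus_id = paste0("L", seq_along(seqs)),
    chrom = "chr1", start = 0L, end = len, strand = "+", side = "upstream",
    anchor_site = 0L, tag_17 = substr(seqs, 1L, 17L), tag_18 = seqs,
    stringsAsFactors = FALSE)
  virtual_tag_library(ent, "MMSDK")
}

# brute-force mapper mirroring the contract: match as 18-mer (both
# orientations, min distance, unique best) then fall back to the 17-mer
# prefix
brute_map <- function(q, lib, max_mm = 1L) {
  ent <- lib$entries
  try_len <- function(qq, col) {
    refs <- ent[[col]]
    d <- pmin(vapply(refs, hamming, numeric(1), a = qq),
              vapply(refs, hamming, numeric(1), a = rev_comp(qq)))
    dm <- min(d)
    if (dm > max_mm) return(NULL)
    hits <- which(d == dm)
    list(n = length(hits), locus = ent$locus_id[hits[1]], d = dm)
  }
  res <- if (nchar(q) >= 18L) try_len(substr(q, 1L, 18L), "tag_18") else NULL
  if (is.null(res) && nchar(q) >= 17L) res <- try_len(substr(q, 1L, 17L), "tag_17")
  if (is.null(res)) return(list(status = "unmapped"))
  if (res$n > 1L) return(list(status = "ambiguous"))
  list(status = "mapped", locus = res$locus, d = res$d)
}

empty_mmsdk_entries_for_test <- function() {
  data.frame(tag_id = character(0), locus_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             side = character(0), anchor_site = integer(0),
             tag_17 = character(0), tag_18 = character(0), stringsAsFactors = FALSE)
}
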