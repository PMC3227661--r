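adapter_fixture <- "TCGTATGCCGTCTTCTGCTTG"

test_that("adapter clipping handles exact, mutated and absent adapters", {
  tag <- "ACGTACGTACGTACGTAC"  # 18 bases
  expect_identical(clip_adapter(paste0(tag, adapter_fixture), adapter_fixture), tag)
  # truncated adapter at the read end still clips once score >= 7
  expect_identical(clip_adapter(paste0(tag, substr(adapter_fixture, 1, 9)),
                                adapter_fixture), tag)
  # read with no adapter similarity is unchanged
  expect_identical(clip_adapter(tag, adapter_fixture), tag)
  # empty read and empty adapter are no-ops; short adapters are rejected
  expect_identical(clip_adapter("", adapter_fixture), "")
  expect_identical(clip_adapter(tag, ""), tag)
  expect_error(clip_adapter(tag, "ACGTA"), "at least 6")
})

test_that("clipping matches brute-force suffix scoring under substitutions", {
  brute_clip <- function(read, adapter, mt = 1, mm = -1, gp = -2, min_score = 7) {
    r <- strsplit(read, "")[[1]]; a <- strsplit(adapter, "")[[1]]
    best <- -Inf; bi <- NA
    for (i in seq_along(r)) {
      s <- r[i:length(r)]; n <- length(s); m <- length(a)
      F <- matrix(-Inf, n + 1, m + 1)
      F[1, ] <- (0:m) * gp; F[, 1] <- (0:n) * gp
      for (p in 1:n) for (q in 1:m) {
        F[p + 1, q + 1] <- max(F[p, q] + ifelse(s[p] == a[q], mt, mm),
                               F[p, q + 1] + gp, F[p + 1, q] + gp)
      }
      sc <- max(F[n + 1, ])
      if (sc > best) { best <- sc; bi <- i }
    }
    if (best >= min_score) substr(read, 1, bi - 1) else read
  }
  set.seed(5)
  for (i in 1:40) {
    tag <- random_dna(sample(17:22, 1), 0.5)
    a <- strsplit(adapter_fixture, "")[[1]]
    nmut <- sample(0:2, 1)
    if (nmut) for (p in sample(seq_along(a), nmut)) {
      a[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1)
    }
    read <- paste0(tag, paste(a[1:sample(7:21, 1)], collapse = ""))
    expect_identical(clip_adapter(read, adapter_fixture),
                     brute_clip(read, adapter_fixture))
  }
})

test_that("clipping is idempotent on simulated tag reads", {
  set.seed(6)
  reads <- paste0(replicate(200, random_dna(18, 0.5)), adapter_fixture)
  once <- clip_adapter(reads, adapter_fixture)
  expect_identical(clip_adapter(once, adapter_fixture), once)
})

test_that("read filtering applies the N, length, singleton and quality rules", {
  rs <- read_set(c("ACGTNACGT", "ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC",
                   "TTTTTTTTTTTTTTTTTT", "ACGTACGTACGTACGTA"))
  # N-containing reads go
  f <- filter_reads(rs, drop_n = TRUE)
  expect_false(any(grepl("N", f$reads$seq)))
  # miRNA mode: length floor at 18
  f <- filter_reads(rs, min_len = 18L)
  expect_true(all(nchar(f$reads$seq) >= 18L))
  # mRNA mode: single-copy sequences go, multiplicity survives
  f <- filter_reads(rs, drop_singletons = TRUE)
  expect_equal(f$reads$seq, "ACGTACGTACGTACGTAC")
  expect_equal(f$reads$count, 2L)
  # mean quality below Q20 drops the read when qualities are present
  rq <- read_set(c("AAAA", "CCCC"), c(1L, 1L), mean_quality = c(30, 10))
  expect_equal(filter_reads(rq)$reads$seq, "AAAA")
})

test_that("mapper agrees with the brute-force Hamming oracle (both tag forms)", {
  lib <- toy_tag_library(150, seed = 11)
  set.seed(12)
  bases <- c("A", "C", "G", "T")
  for (i in 1:120) {
    q <- sample(lib$entries$tag_18, 1)
    nmut <- sample(0:2, 1)
    if (nmut) for (p in sample(1:18, nmut)) {
      substr(q, p, p) <- sample(setdiff(bases, substr(q, p, p)), 1)
    }
    if (runif(1) < 0.25) q <- substr(q, 1, 17)        # 17-nt tag form
    if (runif(1) < 0.3) q <- rev_comp(q)              # orientation stress
    got <- map_tags(q, lib)
    want <- brute_map(q, lib)
    expect_identical(got$status, want$status)
    if (want$status == "mapped") {
      expect_identical(got$locus_id, want$locus)
      expect_identical(as.integer(got$distance), as.integer(want$d))
    }
  }
})

test_that("ambiguous tags are discarded and conservation holds", {
  ent <- data.frame(
    tag_id = c("t1", "t2"), locus_id = c("L1", "L2"), chrom = "chr1",
    start = 0L, end = 18L, strand = "+", side = "upstream", anchor_site = 0L,
    tag_17 = c(strrep("A", 17), strrep("A", 17)),
    tag_18 = c(paste0(strrep("A", 17), "C"), paste0(strrep("A", 17), "G")),
    stringsAsFactors = FALSE)
  lib <- virtual_tag_library(ent, "MMSDK")
  # 0 mismatches to both entries at 17; 1 mismatch to both at 18
  res <- map_tags(paste0(strrep("A", 17), "T"), lib)
  expect_identical(res$status, "ambiguous")
  # distance 2 from everything: unmapped
  res2 <- map_tags(paste0(strrep("A", 15), "TTT"), lib)
  expect_identical(res2$status, "unmapped")
  # conservation over a mixed multiset
  reads <- read_set(c(ent$tag_18[1], ent$tag_18[1], paste0(strrep("A", 17), "T"),
                      "ACGTACGTACGTACGTAC"))
  res3 <- map_tags(reads, lib)
  expect_identical(sum(res3$count), 4L)
  expect_setequal(res3$status, c("mapped", "ambiguous", "unmapped"))
})

test_that("empty libraries warn and leave all tags unmapped", {
  lib <- virtual_tag_library(empty_mmsdk_entries_for_test(), "MMSDK")
  expect_warning(res <- map_tags("ACGTACGTACGTACGTAC", lib), "empty")
  expect_identical(res$status, "unmapped")
})

test_that("per-locus counting is additive and keeps zero-count loci", {
  lib <- toy_tag_library(5, seed = 31)
  ent <- lib$entries
  # two entries of one locus: 3 + 2 reads pool to 5
  ent$locus_id[2] <- ent$locus_id[1]
  lib2 <- virtual_tag_library(ent, "MMSDK")
  reads <- read_set(rep(c(ent$tag_18[1], ent$tag_18[2]), c(3L, 2L)))
  tcm <- count_per_locus(list(s1 = map_tags(reads, lib2)), lib2, "tumor")
  expect_equal(unname(tcm$counts[ent$locus_id[1], 1]), 5L)
  expect_true(all(rownames(tcm$counts) == lib2$loci))
  expect_equal(sum(tcm$counts[, 1] == 0L), length(lib2$loci) - 1L)
  expect_equal(unname(tcm$library_sizes), 5)
})

test_that("pooling averages with half-up rounding", {
  m <- matrix(c(2L, 4L, 6L,
                1L, 2L, 0L,
                0L, 0L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("t1", "t2", "t3")))
  tcm <- tag_count_matrix(m, rep("tumor", 3))
  p <- pool_by_mean(tcm, "tumor")
  expect_equal(unname(p$counts), c(4L, 1L, 0L))
  # (1 + 2)/2 = 1.5 rounds half-up to 2
  tcm2 <- tag_count_matrix(m[, 1:2], rep("tumor", 2))
  expect_equal(unname(pool_by_mean(tcm2, "tumor")$counts[2]), 2L)
  expect_error(pool_by_mean(tcm, "normal"), "no samples")
})

test_that("blacklisted intervals remove tags with per-category tallies", {
  asgn <- data.frame(chrom = "chr1", start = c(10L, 100L, 500L),
                     end = c(28L, 118L, 518L), count = c(5L, 2L, 7L),
                     stringsAsFactors = FALSE)
  bl <- list(rRNA = data.frame(chrom = "chr1", start = 0L, end = 50L),
             tRNA = data.frame(chrom = "chr1", start = 90L, end = 130L))
  out <- filter_blacklist(asgn, bl)
  expect_equal(out$start, 500L)
  expect_equal(attr(out, "removed"), c(rRNA = 5L, tRNA = 2L))
  # empty blacklist is the identity
  id <- filter_blacklist(asgn, list())
  expect_equal(nrow(id), 3L)
})
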