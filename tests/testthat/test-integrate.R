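test_that("methylation direction inverts the tag ratio sign on a grid", {
  expect_identical(classify_direction(-1.43), "hypermethylated")
  expect_identical(classify_direction(1.08), "hypomethylated")
  expect_identical(classify_direction(0), "none")
  grid <- seq(-3, 3, by = 0.25)
  got <- classify_direction(grid)
  expect_identical(got[grid <= -1], rep("hypermethylated", sum(grid <= -1)))
  expect_identical(got[grid >= 1], rep("hypomethylated", sum(grid >= 1)))
  expect_identical(got[abs(grid) < 1], rep("none", sum(abs(grid) < 1)))
})

joint_fixture <- function() {
  meth <- data.frame(
    locus_id = c("l_hic1", "l_rasal1", "l_methonly", "l_weak", "l_multi_a", "l_multi_b"),
    log2_ratio = c(-1.43, 1.11, -2.0, -0.4, -1.2, -3.0),
    p_value = c(3.2e-13, 1.99e-7, 1e-9, 0.4, 1e-4, 1e-6),
    fdr = c(4.94e-11, 1.02e-5, 1e-8, 0.6, 1e-3, 1e-5),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    tag_direction = c("down", "up", "down", "down", "down", "down"),
    stringsAsFactors = FALSE)
  expr <- data.frame(
    locus_id = c("HIC1", "RASAL1", "METHONLY", "WEAK", "MULTI"),
    log2_ratio = c(-1.84, 3.69, 0.1, -2.5, 2.2),
    p_value = c(3.98e-5, 5.31e-4, 0.8, 1e-6, 1e-7),
    fdr = c(2.313e-4, 2.42e-3, 0.9, 1e-5, 1e-6),
    significant = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    tag_direction = c("down", "up", "none", "down", "up"),
    stringsAsFactors = FALSE)
  annotation <- data.frame(
    locus_id = c("l_hic1", "l_rasal1", "l_methonly", "l_weak", "l_multi_a",
                 "l_multi_b", "l_orphan"),
    region_class = "CGI-promoter",
    gene_ids = c("HIC1", "RASAL1", "METHONLY", "WEAK", "MULTI", "MULTI", ""),
    stringsAsFactors = FALSE)
  list(meth = meth, expr = expr, annotation = annotation)
}

test_that("gene-level join categorizes direction pairs like the printed examples", {
  x <- joint_fixture()
  j <- join_meth_expr(x$meth, x$expr, x$annotation)
  # tag ratio -1.43 + repressed expression: hypermethylated and repressed
  hic1 <- j[j$gene_id == "HIC1", ]
  expect_identical(hic1$meth_call, "hypermethylated")
  expect_identical(hic1$category, "hyper-repressed")
  # tag ratio +1.11 + induced expression: hypomethylated and induced
  rasal1 <- j[j$gene_id == "RASAL1", ]
  expect_identical(rasal1$meth_call, "hypomethylated")
  expect_identical(rasal1$category, "hypo-induced")
  # significant in methylation only: category ns
  expect_identical(j$category[j$gene_id == "METHONLY"], "ns")
  # methylation not significant: ns even with strong expression
  expect_identical(j$category[j$gene_id == "WEAK"], "ns")
})

test_that("multi-locus genes collapse to their most significant locus", {
  x <- joint_fixture()
  j <- join_meth_expr(x$meth, x$expr, x$annotation)
  multi <- j[j$gene_id == "MULTI", ]
  expect_identical(multi$locus_id, "l_multi_b")  # smaller p-value wins
  expect_equal(multi$meth_log2, -3.0)
  # p-value tie resolves to the larger |log2|
  meth2 <- x$meth
  meth2$p_value[meth2$locus_id %in% c("l_multi_a", "l_multi_b")] <- 1e-6
  j2 <- join_meth_expr(meth2, x$expr, x$annotation)
  expect_identical(j2[j2$gene_id == "MULTI", "locus_id"], "l_multi_b")
})

test_that("join conservation and order invariance hold", {
  x <- joint_fixture()
  j <- join_meth_expr(x$meth, x$expr, x$annotation)
  expect_lte(nrow(j), min(length(unique(x$expr$locus_id)),
                          length(unique(x$annotation$gene_ids))))
  perm <- join_meth_expr(x$meth[sample(nrow(x$meth)), ],
                         x$expr[rev(seq_len(nrow(x$expr))), ], x$annotation)
  expect_equal(j, perm, ignore_attr = TRUE)
  expect_equal(attr(j, "dropped_loci"), 0L)  # orphan locus is not in meth
})

test_that("hypergeometric enrichment matches direct summation", {
  universe <- paste0("g", 1:20)
  gs <- list(term1 = paste0("g", c(1:3, 10, 11)),      # K = 5
             zero_overlap = paste0("g", 15:18),
             with_outside = c(paste0("g", 1:2), "not_in_universe"))
  q <- paste0("g", 1:4)
  r <- hypergeom_enrich(q, universe, gs)
  expect_equal(r$p_value[r$term_id == "term1"],
               hyper_oracle(3, 5, 20, 4), tolerance = 1e-12)
  expect_equal(r$p_value[r$term_id == "term1"], 0.0319917, tolerance = 1e-5)
  # overlap zero reports p = 1
  expect_equal(r$p_value[r$term_id == "zero_overlap"], 1)
  # terms intersect with the universe before testing
  expect_equal(r$term_size[r$term_id == "with_outside"], 2L)
  # query = universe forces k = K and p = 1 everywhere
  r2 <- hypergeom_enrich(universe, universe, gs)
  expect_true(all(r2$p_value == 1))
  # offending query genes are named
  expect_error(hypergeom_enrich(c("g1", "nope"), universe, gs), "nope")
})

test_that("enrichment p-values match the oracle over random instances", {
  set.seed(37)
  universe <- paste0("g", 1:60)
  for (i in 1:200) {
    K <- sample(1:30, 1); n <- sample(1:30, 1)
    gs <- list(t = sample(universe, K))
    q <- sample(universe, n)
    r <- hypergeom_enrich(q, universe, gs)
    k <- length(intersect(gs$t, q))
    expect_equal(r$p_value, hyper_oracle(k, K, 60, n), tolerance = 1e-12)
  }
})

test_that("genome tracks export in coordinate order with a threshold header", {
  layers <- list(
    methylation = data.frame(chrom = c("chr2", "chr1", "chr1"),
                             start = c(5L, 100L, 7L), end = c(11L, 106L, 13L),
                             log2_ratio = c(0.5, -1.43, 2.0)),
    mrna = data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), log2_ratio = numeric(0)))
  path <- tempfile(fileext = ".bedgraph")
  export_genome_track(layers, path)
  lines <- readLines(path)
  expect_match(lines[1], "log2Ratio\\| = 1")
  expect_match(lines[2], "methylation")
  body <- lines[3:5]
  expect_equal(body, c("chr1\t7\t13\t2", "chr1\t100\t106\t-1.43", "chr2\t5\t11\t0.5"))
  expect_match(lines[6], "mrna")
  expect_length(lines, 6L)
})

test_that("GMT collections round-trip", {
  gs <- list(alpha = c("g1", "g2", "g3"), beta = c("g9"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  expect_equal(read_gmt(path), gs)
})
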