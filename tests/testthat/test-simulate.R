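test_that("simulated genomes are seed-deterministic and motif-exact", {
  cfg <- sim_config(genome_length = 60000, n_chromosomes = 2, n_mlu_sites = 50,
                    n_genes = 10, n_cgis = 5, seed = 1)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$planted_site_positions, g2$truth$planted_site_positions)

  # planted MluI sites are exactly the sites a brute-force scan finds
  for (chrom in names(g1$genome)) {
    expect_identical(naive_scan(as.character(g1$genome[[chrom]]), "ACGCGT"),
                     as.integer(g1$truth$planted_site_positions[[chrom]]))
  }
  expect_equal(sum(lengths(g1$truth$planted_site_positions)), 50L)

  # every planted site is flanked by a CATG within 30-500 bases on each side
  for (chrom in names(g1$genome)) {
    s <- as.character(g1$genome[[chrom]])
    catg <- naive_scan(s, "CATG")
    for (p in g1$truth$planted_site_positions[[chrom]]) {
      left_gap <- (p + 1L) - (catg + 4L)   # NlaIII cut to MluI cut distance
      right_gap <- catg - (p + 6L)         # MluI motif end to CATG start
      expect_true(any(left_gap >= 31L & left_gap <= 501L))
      expect_true(any(right_gap >= 30L & right_gap <= 500L))
    }
  }
})

test_that("a null config yields a genome with zero MluI motifs", {
  cfg <- sim_config(genome_length = 30000, n_chromosomes = 1, n_mlu_sites = 0,
                    n_genes = 0, n_cgis = 0, seed = 3)
  g <- simulate_genome(cfg)
  expect_identical(naive_scan(as.character(g$genome[[1]]), "ACGCGT"), integer(0))
})

test_that("planted CpG islands satisfy all three criteria on re-check", {
  cfg <- sim_config(genome_length = 60000, n_chromosomes = 1, n_mlu_sites = 10,
                    n_genes = 5, n_cgis = 8, seed = 5)
  g <- simulate_genome(cfg)
  cgis <- g$truth$planted_cgi_intervals
  expect_equal(nrow(cgis), 8L)
  s <- as.character(g$genome[[1]])
  for (i in seq_len(nrow(cgis))) {
    seg <- substr(s, cgis$start[i] + 1L, cgis$end[i])
    ch <- strsplit(seg, "")[[1]]
    L <- length(ch)
    nc <- sum(ch == "C"); ng <- sum(ch == "G")
    ncpg <- sum(ch[-L] == "C" & ch[-1] == "G")
    expect_gt(L, 200)
    expect_gte((nc + ng) / L, 0.5)
    expect_gt(ncpg * L / (nc * ng), 0.6)
  }
})

test_that("infeasible motif packing fails loudly", {
  cfg <- sim_config(genome_length = 3000, n_chromosomes = 1, n_mlu_sites = 50,
                    n_genes = 0, n_cgis = 0, seed = 1)
  expect_error(simulate_genome(cfg), "infeasible")
})

test_that("simulated counts are deterministic, Poisson-calibrated, and spike-free under the null", {
  cfg0 <- sim_config(n_pairs = 4, baseline_rate_mean = 50, n_spiked = 0, seed = 9)
  a <- simulate_counts(cfg0, 300L)
  b <- simulate_counts(cfg0, 300L)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$spiked_locus_ids, character(0))
  expect_true(all(colSums(a$counts$counts) == a$counts$library_sizes))

  # null mean/variance calibration across 1,000 loci
  cfgc <- sim_config(n_pairs = 9, baseline_rate_mean = 100, n_spiked = 0, seed = 2)
  cc <- simulate_counts(cfgc, 1000L)
  m <- cc$counts$counts
  ratio <- mean(apply(m, 1, var)) / mean(rowMeans(m))
  expect_gte(ratio, 0.8)
  expect_lte(ratio, 1.25)
})

test_that("spiked loci shift tumor counts by the configured fold change", {
  cfg <- sim_config(n_pairs = 9, baseline_rate_mean = 200, n_spiked = 40,
                    spike_log2fc = 2, seed = 4)
  sc <- simulate_counts(cfg, 400L)
  m <- sc$counts$counts
  tum <- rowMeans(m[, sc$counts$samples$condition == "tumor"])
  nor <- rowMeans(m[, sc$counts$samples$condition == "normal"])
  up <- names(sc$truth$spike_directions)[sc$truth$spike_directions > 0]
  dn <- names(sc$truth$spike_directions)[sc$truth$spike_directions < 0]
  expect_true(all(abs(log2(tum[up] / nor[up]) - 2) < 0.5))
  expect_true(all(abs(log2(tum[dn] / nor[dn]) + 2) < 0.5))
  null_loci <- setdiff(rownames(m), sc$truth$spiked_locus_ids)
  expect_lt(max(abs(log2(tum[null_loci] / nor[null_loci]))), 1)
})

test_that("error-free reads with an empty adapter are the bare tags", {
  cfg <- sim_config(genome_length = 60000, n_chromosomes = 1, n_mlu_sites = 20,
                    n_genes = 0, n_cgis = 0, n_pairs = 1,
                    baseline_rate_mean = 10, n_spiked = 0, seed = 6)
  g <- simulate_genome(cfg)
  b <- build_mmsdk_library(g$genome, mlu_sites(g$genome), nla_sites(g$genome))
  sc <- simulate_counts(cfg, b$library)
  reads <- simulate_reads(b$library, sc$counts, adapter = "", error_rate = 0, seed = 6)
  allowed <- c(b$library$entries$tag_18, b$library$entries$tag_17)
  for (rs in reads) expect_true(all(rs$reads$seq %in% allowed))
  expect_equal(sum(vapply(reads, n_reads, numeric(1))), sum(sc$counts$counts))
})

test_that("reads with substitution errors recover per-locus counts within 5%", {
  cfg <- sim_config(genome_length = 120000, n_chromosomes = 1, n_mlu_sites = 30,
                    n_genes = 0, n_cgis = 0, n_pairs = 1,
                    baseline_rate_mean = 100, n_spiked = 0, seed = 8)
  g <- simulate_genome(cfg)
  b <- build_mmsdk_library(g$genome, mlu_sites(g$genome), nla_sites(g$genome))
  sc <- simulate_counts(cfg, b$library)
  reads <- simulate_reads(b$library, sc$counts, adapter = "", error_rate = 0.01, seed = 8)
  asgn <- lapply(reads, map_tags, library = b$library)
  tcm <- count_per_locus(asgn, b$library, sc$counts$samples$condition)
  truth <- sc$counts$counts[rownames(tcm$counts), 1]
  got <- tcm$counts[, 1]
  busy <- truth >= 50
  expect_true(all(abs(got[busy] - truth[busy]) / truth[busy] <= 0.05))
})

test_that("adapters shorter than 6 bases are rejected for read simulation", {
  cfg <- sim_config(n_pairs = 1, baseline_rate_mean = 5, n_spiked = 0, seed = 1)
  sc <- simulate_counts(cfg, 5L)
  lib <- toy_tag_library(5)
  lib$entries$locus_id <- rownames(sc$counts$counts)
  lib$loci <- rownames(sc$counts$counts)
  expect_error(simulate_reads(lib, sc$counts, adapter = "ACG"), "at least 6")
})

test_that("the optional overdispersed generator inflates variance beyond Poisson", {
  cfg <- sim_config(n_pairs = 9, baseline_rate_mean = 100, n_spiked = 0,
                    dispersion = 0.2, seed = 2)
  m <- simulate_counts(cfg, 1000L)$counts$counts
  ratio <- mean(apply(m, 1, var)) / mean(rowMeans(m))
  expect_gt(ratio, 1.25)  # clearly super-Poissonian
  expect_error(sim_config(dispersion = -1), "non-negative")
})
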