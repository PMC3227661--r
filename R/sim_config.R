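#' Simulation configuration for the synthetic tumor/normal study
#'
#' Defaults emulate the matched-pair tag-sequencing design the pipeline is
#' built for: 9 tumor/normal pairs, Poisson tag counts with a baseline
#' expectation of 100 tags per locus, and truly differential loci spiked at
#' |log2 fold change| = 2.  Genome-scale parameters are desk-scale stand-ins
#' for a real genome; the statistical structure (planted MluI cassettes
#' flanked by NlaIII sites, CpG islands satisfying the caller's criteria)
#' is what downstream stages consume.
#'
#' @param genome_length Total genome size in bases.
#' @param n_chromosomes Number of chromosomes (length split evenly).
#' @param gc_content Background GC fraction in `[0,1]`.
#' @param n_mlu_sites Planted ACGCGT motifs, each flanked within 30-500
#'   bases on both sides by planted CATG motifs.
#' @param n_genes Simple gene models to plant (annotation only).
#' @param n_cgis CpG-island segments to plant, each satisfying all three
#'   island criteria.
#' @param n_pairs Tumor/normal sample pairs.
#' @param library_size Expected tags per library; when NULL it is implied
#'   by `baseline_rate_mean` times the locus count.
#' @param baseline_rate_mean Expected tags per locus per library.
#' @param n_spiked Number of truly differential loci.
#' @param spike_log2fc Spike magnitude, |log2 fold change| >= 1.
#' @param dispersion Count overdispersion: 0 (default) draws Poisson
#'   counts, matching the differential test's model; a positive value
#'   draws negative-binomial counts with variance `mu + dispersion * mu^2`
#'   for robustness studies only.
#' @param seed Integer seed; fully determines all outputs (per-stage
#'   sub-seeds are derived from it).
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(genome_length = 400000L, n_chromosomes = 2L,
                       gc_content = 0.41, n_mlu_sites = 150L, n_genes = 60L,
                       n_cgis = 30L, n_pairs = 9L, library_size = NULL,
                       baseline_rate_mean = 100, n_spiked = 100L,
                       spike_log2fc = 2, dispersion = 0, seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_chromosomes = as.integer(n_chromosomes),
              gc_content = gc_content,
              n_mlu_sites = as.integer(n_mlu_sites),
              n_genes = as.integer(n_genes), n_cgis = as.integer(n_cgis),
              n_pairs = as.integer(n_pairs), library_size = library_size,
              baseline_rate_mean = baseline_rate_mean,
              n_spiked = as.integer(n_spiked), spike_log2fc = spike_log2fc,
              dispersion = dispersion, seed = as.integer(seed))
  counts <- c("genome_length", "n_chromosomes", "n_mlu_sites", "n_genes",
              "n_cgis", "n_pairs", "n_spiked")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L) stop(f, " must be a non-negative count")
  }
  if (cfg$n_chromosomes < 1L) stop("n_chromosomes must be at least 1")
  if (cfg$gc_content < 0 || cfg$gc_content > 1) stop("gc_content must lie in [0,1]")
  if (cfg$baseline_rate_mean < 0) stop("baseline_rate_mean must be non-negative")
  if (cfg$n_spiked > 0L && cfg$spike_log2fc < 1) {
    stop("spike_log2fc magnitude must be at least 1 when loci are spiked")
  }
  if (cfg$dispersion < 0) stop("dispersion must be non-negative")
  structure(cfg, class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(paste0("SimConfig: %d bp / %d chromosome(s), %d MluI cassettes, ",
                     "%d genes, %d CGIs; %d pairs, rate %.3g, %d spiked at |lfc| %.3g ",
                     "(seed %d)\n"),
              x$genome_length, x$n_chromosomes, x$n_mlu_sites, x$n_genes,
              x$n_cgis, x$n_pairs, x$baseline_rate_mean, x$n_spiked,
              x$spike_log2fc, x$seed))
  invisible(x)
}
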