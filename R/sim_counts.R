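#' Simulate Poisson tag counts for a matched tumor/normal design
#'
#' Each locus gets a baseline Poisson rate (the configured expected tags
#' per locus, or `library_size / n_loci` when a library size is given).
#' `n_spiked` loci are truly differential: their tumor rate is multiplied
#' by `2^(+/- spike_log2fc)` with random sign.  Counts are drawn
#' independently per sample; library sizes are the realized per-sample
#' totals.
#'
#' @param config A [sim_config()] object.
#' @param library Locus universe: a `VirtualTagLibrary`, a character vector
#'   of locus ids, or a single integer (number of loci).
#' @return List with `counts` (a [tag_count_matrix()]) and `truth`
#'   (`SimTruth` with `spiked_locus_ids` and `spike_directions`).
#' @export
simulate_counts <- function(config, library) {
  stopifnot(inherits(config, "SimConfig"))
  loci <- if (inherits(library, "VirtualTagLibrary")) library$loci
          else if (is.character(library)) library
          else if (is.numeric(library) && length(library) == 1L)
            sprintf("locus_%05d", seq_len(library))
          else stop("library must be a VirtualTagLibrary, locus ids, or a locus count")
  n <- length(loci)
  if (n == 0L) stop("library is empty")
  if (config$n_spiked > n) stop("n_spiked exceeds the number of loci")

  lam0 <- if (!is.null(config$library_size)) config$library_size / n
          else config$baseline_rate_mean

  spike <- with_seed(stage_seed(config$seed, "spike"), {
    ids <- if (config$n_spiked) sample(loci, config$n_spiked) else character(0)
    dirs <- if (config$n_spiked) sample(c(1L, -1L), config$n_spiked, replace = TRUE)
            else integer(0)
    list(ids = ids, dirs = stats::setNames(dirs, ids))
  })

  lam_normal <- rep(lam0, n)
  lam_tumor <- lam_normal
  if (config$n_spiked) {
    idx <- match(spike$ids, loci)
    lam_tumor[idx] <- lam_tumor[idx] * 2^(spike$dirs * config$spike_log2fc)
  }

  draw <- if (config$dispersion > 0) {
    function(n_draw, lam) stats::rnbinom(n_draw, mu = lam,
                                         size = 1 / config$dispersion)
  } else {
    function(n_draw, lam) stats::rpois(n_draw, lam)
  }
  m <- with_seed(stage_seed(config$seed, "counts"), {
    k <- config$n_pairs
    tum <- matrix(draw(n * k, lam_tumor), nrow = n)
    nor <- matrix(draw(n * k, lam_normal), nrow = n)
    cbind(tum, nor)
  })
  rownames(m) <- loci
  colnames(m) <- c(sprintf("tumor_%d", seq_len(config$n_pairs)),
                   sprintf("normal_%d", seq_len(config$n_pairs)))
  conditions <- rep(c("tumor", "normal"), each = config$n_pairs)

  truth <- structure(list(spiked_locus_ids = spike$ids,
                          spike_directions = spike$dirs),
                     class = "SimTruth")
  list(counts = tag_count_matrix(m, conditions), truth = truth)
}
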