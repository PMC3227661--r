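#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero (half-up for non-negative values)
#'
#' Pooled tag counts are rounded with the classic half-up rule (1.5 -> 2),
#' not R's banker's rounding.
#'
#' @param x Numeric vector (non-negative in all pipeline uses).
#' @return Numeric vector of integers.
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Deterministic per-stage sub-seed derived from one global seed, so each
# simulation stage can be regenerated independently.  Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stages <- c(
    genome = 1L, cgi = 2L, genes = 3L, rates = 4L, spike = 5L,
    counts = 6L, reads = 7L, errors = 8L, orient = 9L
  )
  idx <- stages[[stage]]
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + idx * 100003) %% 2147483629 + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Collapse a list column of character vectors to comma strings for TSV output.
collapse_ids <- function(x) {
  vapply(x, function(v) paste(v, collapse = ","), character(1))
}
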