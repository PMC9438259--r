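#' Derive a reproducible substream seed
#'
#' A single user-facing integer seed drives a named hierarchy of independent
#' random substreams (genome, truth, reads, ...), so adding or re-running one
#' simulation stage never perturbs the draws of another. The child seed is a
#' deterministic 31-bit hash of the parent seed and the stream name.
#'
#' @param seed Integer parent seed.
#' @param name Character stream name, e.g. `"truth"` or `"reads/rep1"`.
#' @return An integer in `[0, 2^31 - 1]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- (abs(seed) %% m)
  for (b in utf8ToInt(name)) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

#' Evaluate code under a named random substream
#'
#' Runs `code` with the RNG seeded from [substream_seed()], restoring the
#' caller's RNG state afterwards.
#'
#' @param seed Integer parent seed.
#' @param name Stream name.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# internal: match chromosome name to a genome, error if absent
.check_chrom <- function(chrom, genome) {
  bad <- setdiff(unique(chrom), genome$chrom)
  if (length(bad) > 0L) {
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
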