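#' Construct a genome specification
#'
#' A genome is an ordered table of chromosome names and lengths; every other
#' object in the package (tracks, LAD sets, annotations) is defined relative
#' to one.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of chromosome lengths in bp, all positive.
#' @return A `genome_spec`: a data.frame with columns `chrom` and `length`.
#' @export
genome_spec <- function(chrom, length) {
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  g <- data.frame(chrom = as.character(chrom), length = as.numeric(length),
                  stringsAsFactors = FALSE)
  class(g) <- c("genome_spec", "data.frame")
  g
}

#' Simulate a genome
#'
#' Chromosome lengths are drawn uniformly within +/-20% of `mean_length`
#' (rounded to whole bp), emulating the size spread of a small mammalian
#' chromosome set without any sequence content.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param mean_length Mean chromosome length in bp (> 0).
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param jitter Relative half-width of the uniform length jitter (default 0.2).
#' @return A [genome_spec()].
#' @export
make_genome <- function(n_chromosomes, mean_length, seed, jitter = 0.2) {
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1")
  if (mean_length <= 0) stop("mean_length must be positive")
  lens <- with_substream(seed, "genome", {
    round(mean_length * stats::runif(n_chromosomes, 1 - jitter, 1 + jitter))
  })
  genome_spec(paste0("chr", seq_len(n_chromosomes)), lens)
}

# named lengths vector, convenient for lookups
genome_lengths <- function(genome) {
  stats::setNames(genome$length, genome$chrom)
}
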