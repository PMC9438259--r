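#' Count reads at GATC fragment ends into genomic bins
#'
#' A read is counted iff its position coincides exactly with a GATC cut
#' position (a fragment end); it increments the bin containing that
#' position. Reads not at any cut are tallied in the `skipped_reads`
#' attribute, never silently dropped.
#'
#' @param reads A read set from [simulate_reads()] (or any list with a
#'   `records` data.frame of `chrom`, `pos`).
#' @param gatc A [make_gatc_map()] fragment map.
#' @param genome A [genome_spec()].
#' @param bin_size Bin width in bp (default 10 kb, the standard resolution
#'   for nuclear-lamina interaction maps).
#' @return A count [binned_track()] with attribute `skipped_reads`.
#' @export
count_reads_in_bins <- function(reads, gatc, genome, bin_size = 1e4) {
  recs <- reads$records
  .check_chrom(recs$chrom, genome)
  lens <- genome_lengths(genome)
  if (nrow(recs) > 0 &&
      any(recs$pos < 0 | recs$pos >= lens[recs$chrom])) {
    stop("read positions out of chromosome bounds")
  }
  skipped <- 0L
  values <- lapply(genome$chrom, function(ch) {
    n <- ceiling(lens[[ch]] / bin_size)
    counts <- integer(n)
    pos <- recs$pos[recs$chrom == ch]
    if (length(pos) > 0L) {
      at_cut <- pos %in% gatc$cuts[[ch]]
      skipped <<- skipped + sum(!at_cut)
      idx <- bin_index(pos[at_cut], bin_size)
      tab <- tabulate(idx, nbins = n)
      counts <- counts + tab
    }
    counts
  })
  names(values) <- genome$chrom
  if (skipped > 0L) {
    message(skipped, " read(s) not at a GATC cut position were not counted")
  }
  tr <- binned_track(values, bin_size, genome, "count")
  attr(tr, "skipped_reads") <- skipped
  tr
}

#' Normalize a count track to counts per million
#'
#' @param track A count [binned_track()].
#' @return A cpm track; unmasked values sum to 1e6.
#' @export
cpm_normalize <- function(track) {
  if (track$kind != "count") stop("cpm_normalize expects a count track")
  total <- sum(track_values(track), na.rm = TRUE)
  if (total <= 0) stop("zero-total sample cannot be cpm-normalized")
  track_map(track, function(v) v * 1e6 / total, "cpm")
}

#' log2 ratio of LaminB1 over Dam control
#'
#' `log2((lamin + pseudocount) / (dam + pseudocount))`; a mask in either
#' channel propagates.
#'
#' @param lamin,dam cpm [binned_track()]s on the same grid.
#' @param pseudocount Added to both channels before the ratio (default 1).
#' @return A log2-ratio [binned_track()].
#' @export
log2_ratio <- function(lamin, dam, pseudocount = 1) {
  .check_same_grid(lamin, dam)
  values <- mapply(function(l, d) log2((l + pseudocount) / (d + pseudocount)),
                   lamin$values, dam$values, SIMPLIFY = FALSE)
  binned_track(values, lamin$bin_size, lamin$genome, "log2ratio")
}

#' Convert a log2-ratio track to z-scores
#'
#' Centers and scales by the genome-wide mean and sample standard deviation
#' (n - 1) over all unmasked bins, correcting for dynamic-range differences
#' between experiments.
#'
#' @param track A log2-ratio [binned_track()].
#' @return A z-score track with unmasked mean 0 and sd 1.
#' @export
to_zscore <- function(track) {
  v <- track_values(track)
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least 2 unmasked bins")
  s <- stats::sd(v)
  if (s == 0) stop("zero variance: cannot compute z-scores")
  m <- mean(v)
  track_map(track, function(x) (x - m) / s, "zscore")
}

#' Average z-score tracks across biological replicates
#'
#' Per-bin mean over replicates with an unmasked value there; a bin stays
#' masked only if masked in every replicate.
#'
#' @param tracks Non-empty list of z-score [binned_track()]s on one grid.
#' @return The replicate-averaged z-score track.
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) == 0L) stop("empty replicate list")
  for (t in tracks[-1]) .check_same_grid(tracks[[1]], t)
  values <- lapply(names(tracks[[1]]$values), function(ch) {
    m <- sapply(tracks, function(t) t$values[[ch]])
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    out <- rowMeans(m, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
    out
  })
  names(values) <- names(tracks[[1]]$values)
  binned_track(values, tracks[[1]]$bin_size, tracks[[1]]$genome, "zscore")
}

#' Fold change in the linear signal per z-score unit
#'
#' Diagnostic regression of the log2 linear ratio on the z-score over
#' unmasked bins; returns `2^slope`, the multiplicative change in the linear
#' pA-DamID score corresponding to a differential z-score of 1. This checks
#' the dynamic range of an experiment; it is not a calibration constant used
#' anywhere in the pipeline.
#'
#' @param zr A z-score [binned_track()].
#' @param linear_ratio A track of linear LaminB1/Dam ratios on the same grid.
#' @return Fold change per z unit (numeric scalar).
#' @export
estimate_fold_per_z <- function(zr, linear_ratio) {
  .check_same_grid(zr, linear_ratio)
  z <- track_values(zr)
  r <- track_values(linear_ratio)
  keep <- !is.na(z) & !is.na(r) & r > 0
  z <- z[keep]
  y <- log2(r[keep])
  if (length(z) < 3L || stats::sd(z) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: no variance to regress on")
  }
  slope <- stats::cov(y, z) / stats::var(z)
  2^slope
}
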