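#' Construct a binned signal track
#'
#' The universal signal carrier: per chromosome, a vector of values over
#' fixed-width bins tiling the chromosome from position 0 (0-based,
#' half-open). The final partial bin is kept. `NA` marks masked bins, which
#' carry no value and are excluded from all moments and means.
#'
#' @param values Named list of numeric vectors, one per chromosome, each of
#'   length `ceiling(chrom_length / bin_size)`.
#' @param bin_size Bin width in bp.
#' @param genome A [genome_spec()].
#' @param kind Semantics tag: one of `"count"`, `"cpm"`, `"log2ratio"`,
#'   `"zscore"`, `"other"`.
#' @return A `binned_track` object.
#' @export
binned_track <- function(values, bin_size, genome, kind = "other") {
  kind <- match.arg(kind, c("count", "cpm", "log2ratio", "zscore", "other"))
  if (bin_size <= 0) stop("bin_size must be positive")
  .check_chrom(names(values), genome)
  expected <- ceiling(genome_lengths(genome) / bin_size)
  for (ch in names(values)) {
    if (length(values[[ch]]) != expected[[ch]]) {
      stop("chromosome ", ch, ": expected ", expected[[ch]], " bins, got ",
           length(values[[ch]]))
    }
  }
  if (kind == "count") {
    v <- unlist(values, use.names = FALSE)
    v <- v[!is.na(v)]
    if (any(v < 0) || any(v != round(v))) {
      stop("count tracks must hold non-negative integers")
    }
  }
  structure(list(values = values, bin_size = bin_size,
                 genome = genome, kind = kind),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  n <- sum(lengths(x$values))
  nm <- sum(is.na(unlist(x$values, use.names = FALSE)))
  cat(sprintf("binned_track [%s]: %d chromosome(s), bin %d bp, %d bins (%d masked)\n",
              x$kind, length(x$values), as.integer(x$bin_size), n, nm))
  invisible(x)
}

# bin centers of one chromosome (bp)
bin_centers <- function(track, chrom) {
  n <- length(track$values[[chrom]])
  (seq_len(n) - 0.5) * track$bin_size
}

# 0-based bin index holding position(s) pos
bin_index <- function(pos, bin_size) floor(pos / bin_size) + 1L

# assert two tracks share genome and grid
.check_same_grid <- function(a, b) {
  if (a$bin_size != b$bin_size ||
      !identical(names(a$values), names(b$values)) ||
      !identical(lengths(a$values), lengths(b$values))) {
    stop("tracks are on different bin grids")
  }
  invisible(TRUE)
}

# all values as one vector (masked included as NA)
track_values <- function(track) unlist(track$values, use.names = FALSE)

# apply f element-wise, preserving structure; kind must be supplied
track_map <- function(track, f, kind) {
  binned_track(lapply(track$values, f), track$bin_size, track$genome, kind)
}

#' Write a track as bedGraph
#'
#' Masked bins are omitted. Coordinates are 0-based half-open; the final
#' partial bin is clipped at the chromosome end.
#'
#' @param track A [binned_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lens <- genome_lengths(track$genome)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    keep <- which(!is.na(v))
    if (length(keep) == 0L) next
    start <- (keep - 1) * track$bin_size
    end <- pmin(keep * track$bin_size, lens[[ch]])
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, as.integer(start),
                       as.integer(end), format(v[keep], digits = 10,
                                               scientific = FALSE,
                                               trim = TRUE)), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a binned track
#'
#' Intervals must lie on the stated bin grid; absent bins become masked.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param genome A [genome_spec()].
#' @param bin_size Bin width in bp.
#' @param kind Semantics tag for the resulting track.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, genome, bin_size, kind = "other") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  .check_chrom(df$chrom, genome)
  if (any(df$start %% bin_size != 0)) stop("intervals not on the bin grid")
  lens <- genome_lengths(genome)
  values <- lapply(genome$chrom, function(ch) {
    rep(NA_real_, ceiling(lens[[ch]] / bin_size))
  })
  names(values) <- genome$chrom
  idx <- bin_index(df$start, bin_size)
  for (i in seq_len(nrow(df))) {
    values[[df$chrom[i]]][idx[i]] <- df$value[i]
  }
  binned_track(values, bin_size, genome, kind)
}
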