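#' Construct a LAD set
#'
#' Sorted, non-overlapping genomic intervals (0-based, half-open) labelled
#' as lamina-associated domains.
#'
#' @param chrom,start,end Interval coordinates.
#' @param genome A [genome_spec()].
#' @param provenance Optional label (condition, model id).
#' @return A `lad_set` data.frame with columns `chrom`, `start`, `end`.
#' @export
lad_set <- function(chrom, start, end, genome, provenance = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  .check_chrom(df$chrom, genome)
  lens <- genome_lengths(genome)
  if (nrow(df) > 0) {
    if (any(df$start < 0 | df$end > lens[df$chrom] | df$start >= df$end)) {
      stop("invalid LAD intervals")
    }
    df <- df[order(match(df$chrom, genome$chrom), df$start), , drop = FALSE]
    rownames(df) <- NULL
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, ]
      if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)])) {
        stop("overlapping LADs on ", ch)
      }
    }
  }
  structure(df, class = c("lad_set", "data.frame"),
            genome = genome, provenance = provenance)
}

.lads_to_granges <- function(lads) {
  GenomicRanges::GRanges(lads$chrom,
                         IRanges::IRanges(start = lads$start + 1,
                                          end = lads$end))
}

#' Call LADs from a decoded state path
#'
#' The state with the higher emission location is the LAD state; contiguous
#' LAD bins merge into intervals. The result is invariant to relabeling the
#' model's states.
#'
#' @param path State path from [viterbi_segment()].
#' @param model The fitted [hmm_model()].
#' @param track The decoded [binned_track()] (supplies grid and genome).
#' @param provenance Optional label.
#' @return A [lad_set()].
#' @export
call_lads <- function(path, model, track, provenance = NA_character_) {
  if (model$mu[1] == model$mu[2]) {
    stop("emission locations are equal: LAD state is unidentifiable")
  }
  lad_state <- which.max(model$mu)
  lens <- genome_lengths(track$genome)
  rows <- list()
  for (ch in names(path)) {
    r <- rle(path[[ch]] == lad_state)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- which(r$values)
    for (i in keep) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = starts_bin[i] * track$bin_size,
        end = min(ends_bin[i] * track$bin_size, lens[[ch]]),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  lad_set(df$chrom, df$start, df$end, track$genome, provenance)
}

#' Union (consensus) of LAD sets across conditions
#'
#' Interval union with overlapping or book-ended intervals merged, so that
#' LADs appearing in any condition are scored in all of them.
#'
#' @param lad_sets Non-empty list of [lad_set()]s on the same genome.
#' @return A consensus [lad_set()].
#' @export
consensus_lads <- function(lad_sets) {
  if (length(lad_sets) == 0L) stop("no LAD sets given")
  genome <- attr(lad_sets[[1]], "genome")
  all_df <- do.call(rbind, lapply(lad_sets, function(l) {
    data.frame(chrom = l$chrom, start = l$start, end = l$end,
               stringsAsFactors = FALSE)
  }))
  if (nrow(all_df) == 0L) {
    return(lad_set(character(0), numeric(0), numeric(0), genome, "consensus"))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    all_df$chrom, IRanges::IRanges(all_df$start + 1, all_df$end)))
  lad_set(as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
          genome, "consensus")
}

#' Extract oriented borders from a LAD set
#'
#' Each interior LAD contributes two borders; a LAD edge at a chromosome end
#' is not a border. The `side` column records which side of the border is
#' iLAD (`"left"` for a LAD start, `"right"` for a LAD end), so downstream
#' meta-profiles can be oriented LAD-inward.
#'
#' @param lads A [lad_set()].
#' @param genome A [genome_spec()] (defaults to the set's own genome).
#' @return data.frame with columns `chrom`, `pos`, `side`, `lad_id`.
#' @export
extract_borders <- function(lads, genome = attr(lads, "genome")) {
  lens <- genome_lengths(genome)
  rows <- list()
  for (i in seq_len(nrow(lads))) {
    ch <- lads$chrom[i]
    if (lads$start[i] > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = lads$start[i], side = "left", lad_id = i,
        stringsAsFactors = FALSE)
    }
    if (lads$end[i] < lens[[ch]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = lads$end[i], side = "right", lad_id = i,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), pos = numeric(0),
                      side = character(0), lad_id = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write intervals as BED (0-based, half-open)
#'
#' @param df data.frame with `chrom`, `start`, `end` (extra columns appended).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end",
            setdiff(names(df), c("chrom", "start", "end")))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of LADs
#'
#' @param path BED file (chrom, start, end).
#' @param genome A [genome_spec()].
#' @return A [lad_set()].
#' @export
read_lads_bed <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  lad_set(df$chrom, df$start, df$end, genome)
}
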