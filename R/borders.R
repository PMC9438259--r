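#' Bundle site annotations
#'
#' @param ctcf data.frame of CTCF sites: `chrom`, `pos`, `strand`
#'   (`"+"`, `"-"` or `"*"` for unknown motif orientation).
#' @param genes data.frame: `chrom`, `start`, `end`, `strand`, `fpkm`.
#' @param loops data.frame of loop anchor pairs (BEDPE semantics): `chrom1`,
#'   `start1`, `end1`, `chrom2`, `start2`, `end2`.
#' @param genome A [genome_spec()].
#' @return A `site_annotation` list.
#' @export
site_annotation <- function(ctcf = NULL, genes = NULL, loops = NULL, genome) {
  empty <- function(...) {
    df <- data.frame(...)
    df[0, , drop = FALSE]
  }
  if (is.null(ctcf)) {
    ctcf <- empty(chrom = "", pos = 0, strand = "")
  }
  if (is.null(genes)) {
    genes <- empty(chrom = "", start = 0, end = 0, strand = "", fpkm = 0)
  }
  if (is.null(loops)) {
    loops <- empty(chrom1 = "", start1 = 0, end1 = 0,
                   chrom2 = "", start2 = 0, end2 = 0)
  }
  if (any(genes$fpkm < 0)) stop("fpkm must be >= 0")
  .check_chrom(ctcf$chrom, genome)
  .check_chrom(genes$chrom, genome)
  structure(list(ctcf = ctcf, genes = genes, loops = loops, genome = genome),
            class = "site_annotation")
}

#' Convert a ground-truth annotation to a site annotation
#'
#' Loop partners become point anchors widened to `anchor_halfwidth` on each
#' side.
#'
#' @param truth A [place_truth()] annotation.
#' @param anchor_halfwidth Half-width of the synthetic anchor intervals (bp).
#' @return A [site_annotation()].
#' @export
as_site_annotation <- function(truth, anchor_halfwidth = 5e3) {
  looped <- truth$ctcf[!is.na(truth$ctcf$loop_partner), , drop = FALSE]
  loops <- if (nrow(looped) > 0) {
    data.frame(chrom1 = looped$chrom,
               start1 = pmax(looped$pos - anchor_halfwidth, 0),
               end1 = looped$pos + anchor_halfwidth,
               chrom2 = looped$chrom,
               start2 = pmax(looped$loop_partner - anchor_halfwidth, 0),
               end2 = looped$loop_partner + anchor_halfwidth,
               stringsAsFactors = FALSE)
  } else NULL
  site_annotation(ctcf = truth$ctcf[, c("chrom", "pos", "strand")],
                  genes = truth$genes, loops = loops, genome = truth$genome)
}

# distance from positions to an interval (0 if inside)
.dist_to_interval <- function(pos, start, end) {
  pmax(start - pos, pos - end, 0)
}

# oriented window extraction around anchors.
# anchors: data.frame(chrom, pos, inward = +1/-1); offsets are bin-center
# offsets with inward-positive orientation. Returns anchors x offsets matrix.
.extract_windows <- function(track, anchors, flank) {
  bs <- track$bin_size
  if (flank %% bs != 0) stop("flank must be a multiple of bin_size")
  offsets <- seq(-flank + bs / 2, flank - bs / 2, by = bs)
  lens <- genome_lengths(track$genome)
  m <- matrix(NA_real_, nrow = nrow(anchors), ncol = length(offsets))
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    p <- anchors$pos[i] + anchors$inward[i] * offsets
    ok <- p > 0 & p < lens[[ch]]
    idx <- bin_index(p[ok], bs)
    v <- track$values[[ch]]
    ok2 <- idx >= 1L & idx <= length(v)
    m[i, which(ok)[ok2]] <- v[idx[ok2]]
  }
  list(offsets = offsets, matrix = m)
}

.summarize_profile <- function(offsets, m) {
  n <- colSums(!is.na(m))
  mean <- ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
  sd <- apply(m, 2, stats::sd, na.rm = TRUE)
  ci <- ifelse(n > 1, 1.96 * sd / sqrt(n), NA_real_)
  ci[n > 0 & !is.finite(ci)] <- 0
  structure(list(offsets = offsets, mean = mean, ci_half_width = ci,
                 n = n, matrix = m),
            class = "meta_profile")
}

#' Classify LAD borders by CTCF, active genes and loop anchors
#'
#' A border is a CTCF border if a CTCF site lies within `ctcf_window` just
#' outside the LAD (the iLAD side, where CTCF density peaks); it is flagged
#' near an active gene if any gene with FPKM above the threshold has a
#' gene-body edge within `gene_window` on either side, and at a loop anchor
#' if an anchor interval is within `anchor_window`.
#'
#' @param borders Borders from [extract_borders()] (must carry `side`).
#' @param annotation A [site_annotation()].
#' @param ctcf_window Outside window for CTCF sites, bp (default 20 kb).
#' @param gene_window Active-gene window, bp (default 10 kb).
#' @param anchor_window Loop-anchor window, bp (default 20 kb).
#' @param fpkm_threshold Expression threshold for "active" (default 1).
#' @return `borders` with added columns `has_ctcf`, `n_ctcf`,
#'   `orientation_class`, `near_active_gene`, `at_loop_anchor`.
#' @export
classify_borders <- function(borders, annotation, ctcf_window = 2e4,
                             gene_window = 1e4, anchor_window = 2e4,
                             fpkm_threshold = 1) {
  if (is.null(borders$side) || any(!borders$side %in% c("left", "right"))) {
    stop("borders must carry a 'side' direction")
  }
  ctcf <- annotation$ctcf
  act <- annotation$genes[annotation$genes$fpkm > fpkm_threshold, ,
                          drop = FALSE]
  loops <- annotation$loops
  n <- nrow(borders)
  n_ctcf <- integer(n)
  orientation <- character(n)
  near_gene <- logical(n)
  at_anchor <- logical(n)
  for (i in seq_len(n)) {
    b <- borders$pos[i]
    ch <- borders$chrom[i]
    # iLAD side is 'side': left border => iLAD left => outside = [b - w, b)
    s <- ctcf[ctcf$chrom == ch, , drop = FALSE]
    qual <- if (borders$side[i] == "left") {
      s[s$pos >= b - ctcf_window & s$pos < b, , drop = FALSE]
    } else {
      s[s$pos > b & s$pos <= b + ctcf_window, , drop = FALSE]
    }
    n_ctcf[i] <- nrow(qual)
    orientation[i] <- assign_orientation(qual$strand, borders$side[i])
    g <- act[act$chrom == ch, , drop = FALSE]
    near_gene[i] <- nrow(g) > 0 &&
      any(.dist_to_interval(b, g$start, g$end) <= gene_window)
    if (nrow(loops) > 0) {
      a1 <- loops[loops$chrom1 == ch, , drop = FALSE]
      a2 <- loops[loops$chrom2 == ch, , drop = FALSE]
      at_anchor[i] <-
        (nrow(a1) > 0 &&
           any(.dist_to_interval(b, a1$start1, a1$end1) <= anchor_window)) ||
        (nrow(a2) > 0 &&
           any(.dist_to_interval(b, a2$start2, a2$end2) <= anchor_window))
    }
  }
  borders$has_ctcf <- n_ctcf >= 1L
  borders$n_ctcf <- n_ctcf
  borders$orientation_class <- orientation
  borders$near_active_gene <- near_gene
  borders$at_loop_anchor <- at_anchor
  borders
}

#' CTCF motif orientation class of a border
#'
#' `"inward"` if all qualifying sites' motifs point toward the LAD interior,
#' `"outward"` if all point away, `"ambiguous"` if orientations are mixed or
#' any site's motif orientation is unknown, `"none"` if no qualifying site.
#' A `"+"` motif points toward increasing coordinates.
#'
#' @param strands Character vector of qualifying sites' motif strands.
#' @param side Which side of the border is iLAD (`"left"` or `"right"`).
#' @return One of `"inward"`, `"outward"`, `"ambiguous"`, `"none"`.
#' @export
assign_orientation <- function(strands, side) {
  if (length(strands) == 0L) return("none")
  if (any(!strands %in% c("+", "-"))) return("ambiguous")
  # iLAD left => LAD is rightward: '+' points into the LAD
  inward_strand <- if (side == "left") "+" else "-"
  if (all(strands == inward_strand)) return("inward")
  if (all(strands != inward_strand)) return("outward")
  "ambiguous"
}

#' Oriented meta-profile of a track around borders
#'
#' For each border the +/-`flank` window is extracted with the LAD interior
#' at positive offsets; offsets are bin centers relative to the border. The
#' mean and its normal-approximation 95% confidence interval
#' (1.96 * sd / sqrt(n)) are computed per offset over borders with data.
#'
#' @param track A [binned_track()].
#' @param borders Borders (optionally pre-filtered), with `side`.
#' @param flank Half-window in bp, a multiple of the bin size (default
#'   500 kb).
#' @return A `meta_profile`: `offsets`, `mean`, `ci_half_width`, `n`, and
#'   the border x offset `matrix`.
#' @export
metaprofile <- function(track, borders, flank = 5e5) {
  anchors <- data.frame(chrom = borders$chrom, pos = borders$pos,
                        inward = ifelse(borders$side == "left", 1, -1))
  w <- .extract_windows(track, anchors, flank)
  .summarize_profile(w$offsets, w$matrix)
}

#' Change in NL interaction just outside LAD borders
#'
#' Per border: mean z over the bins whose centers lie in `(0,
#' outside_window]` on the iLAD side at time t, minus the same at time 0.
#' This is the region where CTCF-marked borders gain NL interactions upon
#' CTCF loss.
#'
#' @param track_t,track_0 z-score [binned_track()]s on one grid.
#' @param borders Borders with `side`.
#' @param outside_window Averaging window outside the border, bp (default
#'   20 kb).
#' @return Numeric per-border delta z; `NA` where all window bins are masked.
#' @export
border_outside_change <- function(track_t, track_0, borders,
                                  outside_window = 2e4) {
  .check_same_grid(track_t, track_0)
  anchors <- data.frame(chrom = borders$chrom, pos = borders$pos,
                        inward = ifelse(borders$side == "left", 1, -1))
  wt <- .extract_windows(track_t, anchors, outside_window)
  w0 <- .extract_windows(track_0, anchors, outside_window)
  outside <- wt$offsets < 0
  rowMeans(wt$matrix[, outside, drop = FALSE], na.rm = TRUE) -
    rowMeans(w0$matrix[, outside, drop = FALSE], na.rm = TRUE)
}

#' Rank-sum comparison of border groups across timepoints
#'
#' Wilcoxon rank-sum between CTCF and non-CTCF borders per timepoint,
#' Benjamini-Hochberg corrected across timepoints.
#'
#' @param deltas_by_timepoint Named list of per-border delta vectors.
#' @param has_ctcf Logical per border.
#' @return data.frame with group medians, `p_value`, `p_adjusted`.
#' @export
compare_border_groups <- function(deltas_by_timepoint, has_ctcf) {
  rows <- lapply(names(deltas_by_timepoint), function(tp) {
    d <- deltas_by_timepoint[[tp]]
    ok <- !is.na(d)
    x <- d[ok & has_ctcf]
    y <- d[ok & !has_ctcf]
    p <- if (length(x) > 0 && length(y) > 0) {
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    } else NA_real_
    data.frame(timepoint = tp, median_ctcf = stats::median(x),
               median_no_ctcf = stats::median(y), n_ctcf = length(x),
               n_no_ctcf = length(y), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Border shifts relative to a reference segmentation
#'
#' For every condition border, the signed distance to the nearest reference
#' border on the same chromosome; positive = displaced toward the iLAD, as
#' seen from the matched reference border's direction. Pairs farther than
#' `cutoff` are censored to avoid comparisons between different LADs.
#' Equidistant references are broken toward the one with matching direction,
#' then toward the smaller coordinate.
#'
#' @param borders_cond,borders_ref Border tables with `chrom`, `pos`, `side`.
#' @param cutoff Censoring distance in bp (default 100 kb).
#' @return List: `shifts` (per-border table with `distance`, `abs_distance`,
#'   `censored`), `cdf` (ecdf of retained signed distances), `n_censored`.
#' @export
border_shift_cdf <- function(borders_cond, borders_ref, cutoff = 1e5) {
  n <- nrow(borders_cond)
  distance <- rep(NA_real_, n)
  censored <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ch <- borders_cond$chrom[i]
    refs <- borders_ref[borders_ref$chrom == ch, , drop = FALSE]
    if (nrow(refs) == 0L) next
    d_abs <- abs(borders_cond$pos[i] - refs$pos)
    cand <- which(d_abs == min(d_abs))
    if (length(cand) > 1L) {
      match_dir <- cand[refs$side[cand] == borders_cond$side[i]]
      if (length(match_dir) > 0L) cand <- match_dir
      cand <- cand[which.min(refs$pos[cand])]
    }
    j <- cand[1L]
    raw <- borders_cond$pos[i] - refs$pos[j]
    distance[i] <- if (refs$side[j] == "right") raw else -raw
    censored[i] <- abs(distance[i]) > cutoff
  }
  retained <- distance[!censored & !is.na(distance)]
  list(shifts = data.frame(borders_cond, ref_distance = distance,
                           abs_distance = abs(distance),
                           censored = censored),
       cdf = if (length(retained) > 0) stats::ecdf(retained) else NULL,
       n_censored = sum(censored))
}

#' Stratify border deltas by CTCF site count
#'
#' Groups borders by the number of CTCF sites just outside (0, 1, 2, >= 3
#' by default) and summarizes the per-group delta distributions plus a
#' rank-based monotone-trend statistic (Spearman correlation of `n_ctcf`
#' with delta).
#'
#' @param border_anns Classified borders from [classify_borders()].
#' @param deltas Per-border deltas (e.g. from [border_outside_change()]).
#' @param breaks Lower stratum bounds (default `c(0, 1, 2, 3)`; the last is
#'   open-ended).
#' @return List: `groups` (named list of delta vectors), `medians`,
#'   `trend_rho`, `trend_p`.
#' @export
stratify_by_ctcf_count <- function(border_anns, deltas,
                                   breaks = c(0, 1, 2, 3)) {
  stopifnot(nrow(border_anns) == length(deltas))
  labs <- c(paste0(breaks[-length(breaks)]), paste0(">=", breaks[length(breaks)]))
  stratum <- labs[findInterval(border_anns$n_ctcf, breaks)]
  ok <- !is.na(deltas)
  groups <- split(deltas[ok], factor(stratum[ok], levels = labs))
  if (any(lengths(groups) == 0L)) {
    message("empty strata: ",
            paste(names(groups)[lengths(groups) == 0L], collapse = ", "))
  }
  trend <- if (sum(ok) >= 3 && stats::sd(border_anns$n_ctcf[ok]) > 0) {
    suppressWarnings(stats::cor.test(border_anns$n_ctcf[ok], deltas[ok],
                                     method = "spearman"))
  } else NULL
  list(groups = groups,
       medians = vapply(groups, function(g) {
         if (length(g)) stats::median(g) else NA_real_
       }, numeric(1)),
       trend_rho = if (is.null(trend)) NA_real_ else unname(trend$estimate),
       trend_p = if (is.null(trend)) NA_real_ else trend$p.value)
}
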