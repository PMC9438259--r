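#' Filter CTCF sites for detachment scoring
#'
#' Retains sites inside LADs, at least `min_gene_dist` from any active gene
#' (FPKM above the threshold; distance to the nearest gene-body edge) and at
#' least `min_border_dist` from any LAD border, so transcription- and
#' border-driven detachment does not confound the score.
#'
#' @param sites data.frame of sites: `chrom`, `pos` (extra columns kept).
#' @param genes data.frame: `chrom`, `start`, `end`, `fpkm`.
#' @param lads A [lad_set()].
#' @param borders Borders from [extract_borders()].
#' @param min_gene_dist Minimum distance to active genes, bp (default 100 kb).
#' @param min_border_dist Minimum distance to LAD borders, bp (default
#'   100 kb).
#' @param fpkm_threshold Expression threshold for "active" (default 1).
#' @return The qualifying subset of `sites`.
#' @export
filter_sites <- function(sites, genes, lads, borders,
                         min_gene_dist = 1e5, min_border_dist = 1e5,
                         fpkm_threshold = 1) {
  if (nrow(sites) == 0L) return(sites)
  act <- genes[genes$fpkm > fpkm_threshold, , drop = FALSE]
  keep <- vapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]
    p <- sites$pos[i]
    l <- lads[lads$chrom == ch, , drop = FALSE]
    if (!any(p >= l$start & p < l$end)) return(FALSE)
    b <- borders$pos[borders$chrom == ch]
    if (length(b) > 0 && min(abs(p - b)) < min_border_dist) return(FALSE)
    g <- act[act$chrom == ch, , drop = FALSE]
    if (nrow(g) > 0 &&
        min(.dist_to_interval(p, g$start, g$end)) < min_gene_dist) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
  sites[keep, , drop = FALSE]
}

#' Nuclear-lamina detachment score at sites
#'
#' Difference in mean z between the flanking region (bin centers at
#' `flank_inner` to `flank_outer` from the site, both sides pooled) and the
#' site itself (bin centers within `site_radius`). Positive = the site is
#' locally detached from the lamina. Invariant to adding a constant to the
#' track.
#'
#' @param track A z-score [binned_track()].
#' @param sites data.frame with `chrom`, `pos`.
#' @param site_radius Site window half-width, bp (default 10 kb).
#' @param flank_inner,flank_outer Flank window, bp (defaults 50 and 100 kb).
#' @return Numeric per-site score; `NA` where either window has no data.
#' @export
detachment_score <- function(track, sites, site_radius = 1e4,
                             flank_inner = 5e4, flank_outer = 1e5) {
  if (nrow(sites) == 0L) return(numeric(0))
  bs <- track$bin_size
  lens <- genome_lengths(track$genome)
  vapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]
    p <- sites$pos[i]
    v <- track$values[[ch]]
    centers <- (seq_along(v) - 0.5) * bs
    d <- abs(centers - p)
    site_v <- v[d <= site_radius]
    flank_v <- v[d >= flank_inner & d <= flank_outer]
    if (all(is.na(site_v)) || all(is.na(flank_v))) return(NA_real_)
    mean(flank_v, na.rm = TRUE) - mean(site_v, na.rm = TRUE)
  }, numeric(1))
}

#' Classify sites by chromatin-loop partner location
#'
#' `"no_anchor"` if no loop anchor lies within `anchor_window` of the site;
#' otherwise `"partner_in_iLAD"` or `"partner_in_LAD"` by whether the other
#' anchor of the loop overlaps a LAD. A site at anchors of several loops
#' takes `"partner_in_iLAD"` if any partner is in an iLAD (the
#' most-detaching class dominates).
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @param loops BEDPE-style data.frame (`chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`).
#' @param lads A [lad_set()].
#' @param anchor_window Anchor matching window, bp (default 20 kb).
#' @return Character per-site loop class.
#' @export
classify_loop_partner <- function(sites, loops, lads, anchor_window = 2e4) {
  if (!all(c("chrom1", "start1", "end1", "chrom2", "start2", "end2") %in%
           names(loops))) {
    stop("malformed loop table: need BEDPE columns")
  }
  if (nrow(loops) > 0 &&
      any(loops$start1 > loops$end1 | loops$start2 > loops$end2)) {
    stop("malformed loop intervals")
  }
  in_lad <- function(ch, start, end) {
    l <- lads[lads$chrom == ch, , drop = FALSE]
    nrow(l) > 0 && any(start < l$end & end > l$start)
  }
  vapply(seq_len(nrow(sites)), function(i) {
    ch <- sites$chrom[i]
    p <- sites$pos[i]
    partners <- list()
    for (j in seq_len(nrow(loops))) {
      if (loops$chrom1[j] == ch &&
          .dist_to_interval(p, loops$start1[j], loops$end1[j]) <=
          anchor_window) {
        partners[[length(partners) + 1L]] <-
          c(loops$chrom2[j], loops$start2[j], loops$end2[j])
      }
      if (loops$chrom2[j] == ch &&
          .dist_to_interval(p, loops$start2[j], loops$end2[j]) <=
          anchor_window) {
        partners[[length(partners) + 1L]] <-
          c(loops$chrom1[j], loops$start1[j], loops$end1[j])
      }
    }
    if (length(partners) == 0L) return("no_anchor")
    partner_lad <- vapply(partners, function(a) {
      in_lad(a[1], as.numeric(a[2]), as.numeric(a[3]))
    }, logical(1))
    if (any(!partner_lad)) "partner_in_iLAD" else "partner_in_LAD"
  }, character(1))
}

#' Compare detachment scores between loop classes
#'
#' Pairwise Wilcoxon rank-sum tests between groups, Benjamini-Hochberg
#' corrected, plus group medians and sizes. Singleton groups are flagged.
#'
#' @param records data.frame with `score` and `loop_class` (or any grouping
#'   column named via `group_col`).
#' @param group_col Name of the grouping column (default `"loop_class"`).
#' @return List: `medians`, `n`, `tests` (pairwise table with `p_value`,
#'   `p_adjusted`).
#' @export
compare_detachment_groups <- function(records, group_col = "loop_class") {
  ok <- !is.na(records$score)
  groups <- split(records$score[ok], records[[group_col]][ok])
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < 2L) stop("need at least 2 non-empty groups")
  if (any(lengths(groups) == 1L)) {
    message("singleton group(s): ",
            paste(names(groups)[lengths(groups) == 1L], collapse = ", "))
  }
  pairs <- utils::combn(names(groups), 2)
  tests <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      p_value = apply(pairs, 2, function(pr) {
                        suppressWarnings(stats::wilcox.test(
                          groups[[pr[1]]], groups[[pr[2]]])$p.value)
                      }),
                      stringsAsFactors = FALSE)
  tests$p_adjusted <- stats::p.adjust(tests$p_value, method = "BH")
  list(medians = vapply(groups, stats::median, numeric(1)),
       n = lengths(groups), tests = tests)
}

#' Site-centered meta-profiles for several anchor sets
#'
#' Computes per-offset mean with 95% CI and the site x offset matrix
#' (heatmap-ready, missing data as `NA`) for each anchor set, e.g. active
#' genes, inactive genes, CTCF sites, and random LAD positions. Supply
#' cross-filtered sets (see [filter_min_distance()]) so classes do not
#' contaminate each other.
#'
#' @param track A z-score [binned_track()].
#' @param anchor_sets Named list of data.frames with `chrom`, `pos`.
#' @param flank Half-window in bp, multiple of the bin size (default 200 kb).
#' @return Named list of `meta_profile`s.
#' @export
site_metaprofile <- function(track, anchor_sets, flank = 2e5) {
  lapply(anchor_sets, function(s) {
    anchors <- data.frame(chrom = s$chrom, pos = s$pos, inward = 1)
    w <- .extract_windows(track, anchors, flank)
    .summarize_profile(w$offsets, w$matrix)
  })
}

#' Remove positions close to another position set
#'
#' Keeps rows of `x` at least `min_dist` from every position in `y` (same
#' chromosome); the mutual 100-kb cross-filter used before site-centered
#' profiling.
#'
#' @param x,y data.frames with `chrom`, `pos`.
#' @param min_dist Minimum separation, bp (default 100 kb).
#' @return Filtered `x`.
#' @export
filter_min_distance <- function(x, y, min_dist = 1e5) {
  if (nrow(x) == 0L || nrow(y) == 0L) return(x)
  keep <- vapply(seq_len(nrow(x)), function(i) {
    yp <- y$pos[y$chrom == x$chrom[i]]
    length(yp) == 0L || min(abs(yp - x$pos[i])) >= min_dist
  }, logical(1))
  x[keep, , drop = FALSE]
}

#' Random positions inside LADs
#'
#' Uniform over the LAD bp at least `min_border_dist` from the LAD's own
#' borders; intervals are sampled proportionally to their eligible length.
#'
#' @param lads A [lad_set()].
#' @param n Number of positions.
#' @param min_border_dist Margin from LAD borders, bp.
#' @param seed Integer seed.
#' @return data.frame with `chrom`, `pos`.
#' @export
random_lad_positions <- function(lads, n, min_border_dist = 1e5, seed = 1) {
  elig <- data.frame(chrom = lads$chrom,
                     start = lads$start + min_border_dist,
                     end = lads$end - min_border_dist,
                     stringsAsFactors = FALSE)
  elig <- elig[elig$end > elig$start, , drop = FALSE]
  if (nrow(elig) == 0L) {
    stop("no LAD is large enough for a ", min_border_dist, " bp margin")
  }
  w <- elig$end - elig$start
  with_substream(seed, "random_lad_positions", {
    idx <- sample.int(nrow(elig), n, replace = TRUE, prob = w)
    pos <- floor(stats::runif(n, elig$start[idx], elig$end[idx]))
    data.frame(chrom = elig$chrom[idx], pos = pos, stringsAsFactors = FALSE)
  })
}
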