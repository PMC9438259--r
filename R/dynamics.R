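#' Mean track score per consensus LAD
#'
#' Per-LAD mean over unmasked bins lying fully inside the LAD; partial bins
#' at LAD edges are excluded. LADs with no data give `NA`.
#'
#' @param track A [binned_track()].
#' @param consensus A [lad_set()].
#' @return Numeric vector, one score per LAD (named by LAD index).
#' @export
lad_mean_scores <- function(track, consensus) {
  bs <- track$bin_size
  vapply(seq_len(nrow(consensus)), function(i) {
    v <- track$values[[consensus$chrom[i]]]
    first <- ceiling(consensus$start[i] / bs) + 1L      # first full bin
    last <- floor(consensus$end[i] / bs)                # last full bin
    if (last < first) return(NA_real_)
    vals <- v[first:last]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
}

#' Empirical null thresholds for LAD changes
#'
#' Quantiles (type-7 linear interpolation) of a null delta distribution,
#' e.g. the per-LAD score changes of an untreated control over the same
#' interval.
#'
#' @param pt_deltas Null delta vector (>= 1000 values recommended).
#' @param quantiles Lower/upper tail probabilities (default
#'   `c(0.001, 0.999)`).
#' @return Named numeric `c(low, high)`.
#' @export
null_thresholds <- function(pt_deltas, quantiles = c(0.001, 0.999)) {
  d <- pt_deltas[!is.na(pt_deltas)]
  if (length(d) < 1000L) {
    warning("only ", length(d), " null deltas; thresholds will be noisy")
  }
  q <- stats::quantile(d, quantiles, names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Classify per-LAD changes against null thresholds
#'
#' @param deltas Per-LAD delta z (t minus 0 h).
#' @param thresholds From [null_thresholds()].
#' @return List: `class` (`"up"`, `"down"`, `"stable"`, `NA`),
#'   `fraction_changed` ((up+down)/n over non-missing LADs), `n`.
#' @export
classify_changes <- function(deltas, thresholds) {
  cls <- ifelse(is.na(deltas), NA_character_,
                ifelse(deltas > thresholds[["high"]], "up",
                       ifelse(deltas < thresholds[["low"]], "down",
                              "stable")))
  n <- sum(!is.na(deltas))
  if (n < length(deltas)) {
    message(length(deltas) - n, " LAD(s) without data excluded")
  }
  list(class = cls,
       fraction_changed = if (n > 0) {
         sum(cls %in% c("up", "down")) / n
       } else NA_real_,
       n = n)
}

#' Per-LAD covariates
#'
#' Computes, for each consensus LAD: size (log2 bp), CTCF and active-gene
#' density (count/Mb), mean histone-mark signal over the LAD's bins, local
#' LAD density (fraction of the surrounding 30 Mb classified as LAD,
#' centered on the LAD midpoint and renormalized where the window is clipped
#' at chromosome ends), distances from the LAD midpoint to both chromosome
#' ends and their minimum (Mb), and chromosome size (Mb).
#'
#' @param consensus A [lad_set()].
#' @param annotation A [site_annotation()].
#' @param histone_tracks Named list of [binned_track()]s (e.g. `h3k27me3`,
#'   `h3k9me2`); each yields a `<name>_mean` column.
#' @param genome A [genome_spec()].
#' @param density_window Width of the local-density window, bp (default
#'   30 Mb).
#' @param fpkm_threshold Expression threshold for "active" genes.
#' @return A data.frame with one row per LAD.
#' @export
compute_lad_features <- function(consensus, annotation,
                                 histone_tracks = list(),
                                 genome = attr(consensus, "genome"),
                                 density_window = 3e7, fpkm_threshold = 1) {
  lens <- genome_lengths(genome)
  n <- nrow(consensus)
  size_bp <- consensus$end - consensus$start
  mid <- (consensus$start + consensus$end) / 2
  act <- annotation$genes[annotation$genes$fpkm > fpkm_threshold, ,
                          drop = FALSE]
  ctcf_n <- integer(n)
  gene_n <- integer(n)
  local_density <- numeric(n)
  for (i in seq_len(n)) {
    ch <- consensus$chrom[i]
    s <- consensus$start[i]; e <- consensus$end[i]
    cp <- annotation$ctcf[annotation$ctcf$chrom == ch, , drop = FALSE]
    ctcf_n[i] <- sum(cp$pos >= s & cp$pos < e)
    g <- act[act$chrom == ch, , drop = FALSE]
    gene_n[i] <- sum(g$start < e & g$end > s)
    w0 <- max(mid[i] - density_window / 2, 0)
    w1 <- min(mid[i] + density_window / 2, lens[[ch]])
    l <- consensus[consensus$chrom == ch, , drop = FALSE]
    cov <- sum(pmax(pmin(l$end, w1) - pmax(l$start, w0), 0))
    local_density[i] <- cov / (w1 - w0)
  }
  out <- data.frame(
    lad_id = seq_len(n), chrom = consensus$chrom,
    start = consensus$start, end = consensus$end,
    size_log2_bp = log2(size_bp),
    ctcf_density = ctcf_n / (size_bp / 1e6),
    active_gene_density = gene_n / (size_bp / 1e6),
    local_lad_density = local_density,
    dist_to_start = mid / 1e6,
    dist_to_end = (lens[consensus$chrom] - mid) / 1e6,
    chrom_size = lens[consensus$chrom] / 1e6,
    stringsAsFactors = FALSE)
  out$dist_to_chrom_ends <- pmin(out$dist_to_start, out$dist_to_end)
  for (nm in names(histone_tracks)) {
    out[[paste0(nm, "_mean")]] <- lad_mean_scores(histone_tracks[[nm]],
                                                  consensus)
  }
  rownames(out) <- NULL
  out
}

# Spearman rho with a two-sided p-value: t approximation for n >= 10,
# exact permutation enumeration below that (paper-scale n is always large;
# the exact branch covers toy inputs)
.spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  } else {
    perms <- .permutations(n)
    rx <- rank(x)
    ry <- rank(y)
    # cor(rx, ry[pm]) = (sum(rx * ry[pm]) - n mx my) / ((n-1) sx sy)
    s <- matrix(ry[perms], nrow(perms)) %*% rx
    rhos <- (s - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  c(rho = rho, p = min(p, 1), n = n)
}

# all permutations of 1..n as a matrix (n! rows); used only for tiny n
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlate LAD features with per-condition LAD changes
#'
#' Spearman correlation of each feature column with each condition's delta
#' vector (pairwise-complete), Benjamini-Hochberg corrected across the full
#' matrix; correlations with adjusted p > `alpha` are masked.
#'
#' @param deltas Matrix or data.frame of per-LAD deltas, one column per
#'   condition; rows aligned with `features`.
#' @param features [compute_lad_features()] output; all numeric columns
#'   except coordinates are used.
#' @param alpha Significance level for the mask (default 0.05).
#' @return List of matrices `rho`, `p`, `p_adjusted`, `significant`.
#' @export
correlate_features <- function(deltas, features, alpha = 0.05) {
  deltas <- as.matrix(deltas)
  drop_cols <- c("lad_id", "chrom", "start", "end")
  fcols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                   drop_cols)
  if (nrow(deltas) != nrow(features)) stop("LAD ids do not match")
  rho <- p <- matrix(NA_real_, length(fcols), ncol(deltas),
                     dimnames = list(fcols, colnames(deltas)))
  for (f in fcols) {
    for (j in seq_len(ncol(deltas))) {
      r <- .spearman_test(features[[f]], deltas[, j])
      rho[f, j] <- r[["rho"]]
      p[f, j] <- r[["p"]]
    }
  }
  padj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                 dimnames = dimnames(p))
  list(rho = rho, p = p, p_adjusted = padj,
       significant = !is.na(padj) & padj <= alpha)
}

#' Correlation between conditions' LAD changes
#'
#' @param deltas Matrix of per-LAD deltas, one column per condition (>= 3
#'   LADs).
#' @return Condition x condition Spearman correlation matrix (diagonal 1).
#' @export
correlate_conditions <- function(deltas) {
  deltas <- as.matrix(deltas)
  if (nrow(deltas) < 3L) stop("need at least 3 LADs")
  stats::cor(deltas, method = "spearman", use = "pairwise.complete.obs")
}

#' LAD changes grouped by differential-expression content
#'
#' Groups consensus LADs by whether they contain only upregulated, only
#' downregulated, or no differentially expressed genes; LADs containing both
#' are excluded. Pairwise rank-sum tests between groups with
#' Benjamini-Hochberg correction.
#'
#' @param deltas Per-LAD delta vector aligned with `consensus`.
#' @param consensus A [lad_set()].
#' @param de_genes List with data.frames `up` and `down`, each `chrom`,
#'   `start`, `end`.
#' @return List: `group` per LAD (`"up"`, `"down"`, `"neither"`,
#'   `"excluded"`), `groups` (delta vectors), `medians`, `tests`.
#' @export
diffs_by_de_content <- function(deltas, consensus, de_genes) {
  overlaps_any <- function(i, g) {
    if (is.null(g) || nrow(g) == 0L) return(FALSE)
    gg <- g[g$chrom == consensus$chrom[i], , drop = FALSE]
    nrow(gg) > 0 &&
      any(gg$start < consensus$end[i] & gg$end > consensus$start[i])
  }
  n <- nrow(consensus)
  has_up <- vapply(seq_len(n), overlaps_any, logical(1), g = de_genes$up)
  has_down <- vapply(seq_len(n), overlaps_any, logical(1), g = de_genes$down)
  group <- ifelse(has_up & has_down, "excluded",
                  ifelse(has_up, "up", ifelse(has_down, "down", "neither")))
  ok <- group != "excluded" & !is.na(deltas)
  groups <- split(deltas[ok], factor(group[ok],
                                     levels = c("up", "down", "neither")))
  groups <- groups[lengths(groups) > 0L]
  if (length(groups) < length(c("up", "down", "neither"))) {
    message("empty DE group(s): ",
            paste(setdiff(c("up", "down", "neither"), names(groups)),
                  collapse = ", "))
  }
  tests <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(names(groups), 2)
    tests <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        p_value = apply(pairs, 2, function(pr) {
                          suppressWarnings(stats::wilcox.test(
                            groups[[pr[1]]], groups[[pr[2]]])$p.value)
                        }),
                        stringsAsFactors = FALSE)
    tests$p_adjusted <- stats::p.adjust(tests$p_value, method = "BH")
  }
  list(group = group, groups = groups,
       medians = vapply(groups, stats::median, numeric(1)), tests = tests)
}

#' Expression-matched iLAD control genes
#'
#' Greedy nearest-neighbour matching on log expression without replacement:
#' for each LAD gene, the closest remaining iLAD gene by |log FPKM
#' difference| is taken. Output size equals the LAD gene count, or the pool
#' size if smaller (reported).
#'
#' @param lad_fpkm Expression of the LAD genes (after any minimum-expression
#'   filter; all > 0).
#' @param ilad_fpkm Expression of the candidate iLAD pool (all > 0).
#' @return Integer indices into `ilad_fpkm` of the matched controls.
#' @export
match_expression_controls <- function(lad_fpkm, ilad_fpkm) {
  if (length(lad_fpkm) == 0L) return(integer(0))
  if (length(ilad_fpkm) == 0L) stop("empty iLAD gene pool")
  if (any(lad_fpkm <= 0) || any(ilad_fpkm <= 0)) {
    stop("apply the minimum-expression filter first: all FPKM must be > 0")
  }
  n_take <- min(length(lad_fpkm), length(ilad_fpkm))
  if (n_take < length(lad_fpkm)) {
    message("iLAD pool smaller than LAD gene set: matching ", n_take,
            " of ", length(lad_fpkm))
  }
  lx <- log(lad_fpkm)
  px <- log(ilad_fpkm)
  avail <- rep(TRUE, length(px))
  out <- integer(n_take)
  for (i in seq_len(n_take)) {
    d <- abs(px - lx[i])
    d[!avail] <- Inf
    j <- which.min(d)
    out[i] <- j
    avail[j] <- FALSE
  }
  out
}
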