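#' Describe a depletion-condition effect
#'
#' Encodes how a perturbation reshapes the expected nuclear-lamina
#' interaction profile: scaling of the focal dips at CTCF sites, a signed
#' shift of LAD borders (positive = LAD expands into the iLAD), and an
#' optional LAD-level z offset rule.
#'
#' @param name Condition label.
#' @param dip_multiplier Non-negative scale on CTCF-site dip depth; 0 removes
#'   the dips (complete loss of the focal detachment).
#' @param border_shift Signed border displacement in bp; positive moves each
#'   border outward into the iLAD.
#' @param lad_offset_rule `NULL`, or a function taking the LAD table
#'   (`chrom`, `start`, `end`) and returning one additive z offset per LAD.
#' @return A `condition_effect` list.
#' @export
condition_effect <- function(name, dip_multiplier = 1, border_shift = 0,
                             lad_offset_rule = NULL) {
  if (dip_multiplier < 0) stop("dip_multiplier must be >= 0")
  structure(list(name = name, dip_multiplier = dip_multiplier,
                 border_shift = border_shift,
                 lad_offset_rule = lad_offset_rule),
            class = "condition_effect")
}

#' Construct a ground-truth annotation
#'
#' Bundles hand- or generator-placed LADs, CTCF sites and genes with the
#' shape parameters of the expected profile. Most users want
#' [place_truth()]; this constructor exists for recovery experiments that
#' need exact truths.
#'
#' @param lads data.frame `chrom`, `start`, `end` (bp, non-overlapping).
#' @param ctcf data.frame `chrom`, `pos`, `strand`, `at_border`,
#'   `loop_partner` (NA if unlooped).
#' @param genes data.frame `chrom`, `start`, `end`, `strand`, `fpkm`.
#' @param genome A [genome_spec()].
#' @param dip_depth,dip_width Gaussian dip depth (z) and sd (bp).
#' @param border_halfwidth Logistic 25-75% transition width (bp).
#' @param lad_level,ilad_level Expected z plateau levels.
#' @return A `truth_annotation`.
#' @export
truth_annotation <- function(lads, ctcf = NULL, genes = NULL, genome,
                             dip_depth = 0.5, dip_width = 1e4,
                             border_halfwidth = 2e4,
                             lad_level = 1.0, ilad_level = -0.6) {
  if (is.null(ctcf)) {
    ctcf <- data.frame(chrom = character(0), pos = numeric(0),
                       strand = character(0), at_border = logical(0),
                       loop_partner = numeric(0), stringsAsFactors = FALSE)
  }
  if (is.null(genes)) {
    genes <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0),
                        fpkm = numeric(0), stringsAsFactors = FALSE)
  }
  if (is.null(ctcf$at_border)) ctcf$at_border <- FALSE
  if (is.null(ctcf$loop_partner)) ctcf$loop_partner <- NA_real_
  v <- lad_set(lads$chrom, lads$start, lads$end, genome) # validates + sorts
  lads <- data.frame(chrom = v$chrom, start = v$start, end = v$end,
                     stringsAsFactors = FALSE)
  .check_chrom(ctcf$chrom, genome)
  if (any(genes$fpkm < 0)) stop("fpkm must be >= 0")
  if (dip_depth < 0) stop("dip_depth must be >= 0")
  structure(list(lads = lads, ctcf = ctcf, genes = genes,
                 dip_depth = dip_depth, dip_width = dip_width,
                 border_halfwidth = border_halfwidth,
                 lad_level = lad_level, ilad_level = ilad_level,
                 genome = genome),
            class = "truth_annotation")
}

#' Place ground-truth LADs, CTCF sites and genes on a genome
#'
#' LADs alternate with inter-LAD gaps along each chromosome; LAD and gap
#' lengths are exponential with means `mean_lad_size` and
#' `mean_lad_size * (1 - lad_fraction) / lad_fraction`, so the expected LAD
#' coverage is `lad_fraction`. A configurable fraction of LAD borders carries
#' a CTCF site 5-20 kb outside the LAD (where CTCF density peaks in real
#' maps); further CTCF sites are scattered inside LADs at least 100 kb from
#' borders, and a fraction of those is paired to a loop partner either in a
#' LAD or in the iLAD. Genes are placed genome-wide with log-normal
#' expression; a configurable fraction is silent (FPKM 0).
#'
#' @param genome A [genome_spec()].
#' @param lad_fraction Target fraction of the genome in LADs (0 < f < 1).
#' @param mean_lad_size Mean LAD length in bp.
#' @param ctcf_border_rate Probability that a border carries a CTCF site.
#' @param ctcf_intra_rate Intra-LAD CTCF sites per Mb of LAD.
#' @param gene_rate Genes per Mb, genome-wide.
#' @param dip_depth Depth (z units) of the Gaussian detachment dip at CTCF
#'   sites and active genes.
#' @param seed Integer seed.
#' @param dip_width Gaussian dip standard deviation in bp (default 10 kb).
#' @param border_halfwidth Logistic border transition half-width in bp: the
#'   distance over which the transition runs from 25% to 75% of the step
#'   (default 20 kb).
#' @param lad_level,ilad_level Expected z levels of LAD and iLAD bins.
#' @param loop_fraction Fraction of intra-LAD CTCF sites paired to a loop
#'   partner.
#' @param silent_fraction Fraction of genes with FPKM 0.
#' @param min_border_margin Minimum distance of intra-LAD sites from borders
#'   (bp).
#' @return A `truth_annotation` list with elements `lads`, `ctcf`, `genes`,
#'   dip/border shape parameters and the genome.
#' @export
place_truth <- function(genome, lad_fraction = 0.4, mean_lad_size = 1e6,
                        ctcf_border_rate = 0.7, ctcf_intra_rate = 4,
                        gene_rate = 2, dip_depth = 0.5, seed = 1,
                        dip_width = 1e4, border_halfwidth = 2e4,
                        lad_level = 1.0, ilad_level = -0.6,
                        loop_fraction = 0.5, silent_fraction = 0.4,
                        min_border_margin = 1e5) {
  if (lad_fraction <= 0 || lad_fraction >= 1) {
    stop("lad_fraction must be in (0, 1)")
  }
  mean_gap <- mean_lad_size * (1 - lad_fraction) / lad_fraction
  if (mean_lad_size >= min(genome$length)) {
    stop("mean_lad_size too large for the genome: LAD placement infeasible")
  }
  with_substream(seed, "truth", {
    lads <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
      len <- genome$length[i]
      pos <- round(stats::rexp(1, 1 / mean_gap))
      starts <- numeric(0); ends <- numeric(0)
      repeat {
        lad_len <- max(round(stats::rexp(1, 1 / mean_lad_size)), 1)
        if (pos >= len) break
        end <- min(pos + lad_len, len)
        if (end > pos) { starts <- c(starts, pos); ends <- c(ends, end) }
        pos <- end + round(stats::rexp(1, 1 / mean_gap))
      }
      if (length(starts) == 0L) return(NULL)
      data.frame(chrom = genome$chrom[i], start = starts, end = ends,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(lads) || nrow(lads) == 0L) {
      stop("no LADs placed; densities infeasible for this genome")
    }

    # CTCF sites at borders: 5-20 kb outside the LAD
    ctcf <- NULL
    lens <- genome_lengths(genome)
    for (i in seq_len(nrow(lads))) {
      for (side in c("left", "right")) {
        if (stats::runif(1) >= ctcf_border_rate) next
        off <- stats::runif(1, 5e3, 2e4)
        pos <- if (side == "left") lads$start[i] - off else lads$end[i] + off
        if (pos < 0 || pos >= lens[[lads$chrom[i]]]) next
        ctcf <- rbind(ctcf, data.frame(
          chrom = lads$chrom[i], pos = round(pos),
          strand = sample(c("+", "-"), 1), at_border = TRUE,
          loop_partner = NA_real_, stringsAsFactors = FALSE))
      }
    }

    # intra-LAD CTCF sites, kept >= min_border_margin from borders
    for (i in seq_len(nrow(lads))) {
      span <- lads$end[i] - lads$start[i] - 2 * min_border_margin
      if (span <= 0) next
      n <- stats::rpois(1, ctcf_intra_rate * (lads$end[i] - lads$start[i]) / 1e6)
      if (n == 0L) next
      pos <- round(stats::runif(n, lads$start[i] + min_border_margin,
                                lads$end[i] - min_border_margin))
      looped <- stats::runif(n) < loop_fraction
      partner <- rep(NA_real_, n)
      if (any(looped)) {
        # partner uniform on the chromosome: lands in LAD or iLAD by coverage
        partner[looped] <- round(stats::runif(sum(looped), 0,
                                              lens[[lads$chrom[i]]] - 1))
      }
      ctcf <- rbind(ctcf, data.frame(
        chrom = lads$chrom[i], pos = pos,
        strand = sample(c("+", "-"), n, replace = TRUE), at_border = FALSE,
        loop_partner = partner, stringsAsFactors = FALSE))
    }
    if (is.null(ctcf)) {
      ctcf <- data.frame(chrom = character(0), pos = numeric(0),
                         strand = character(0), at_border = logical(0),
                         loop_partner = numeric(0), stringsAsFactors = FALSE)
    }

    # genes: Poisson per chromosome, log-normal expression
    genes <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
      n <- stats::rpois(1, gene_rate * genome$length[i] / 1e6)
      if (n == 0L) return(NULL)
      glen <- round(stats::runif(n, 5e3, 5e4))
      start <- round(stats::runif(n, 0, genome$length[i] - glen))
      fpkm <- stats::rlnorm(n, meanlog = 1, sdlog = 1.2)
      fpkm[stats::runif(n) < silent_fraction] <- 0
      data.frame(chrom = genome$chrom[i], start = start, end = start + glen,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 fpkm = fpkm, stringsAsFactors = FALSE)
    }))
    if (is.null(genes)) {
      genes <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), strand = character(0),
                          fpkm = numeric(0), stringsAsFactors = FALSE)
    }

    truth_annotation(lads, ctcf, genes, genome,
                     dip_depth = dip_depth, dip_width = dip_width,
                     border_halfwidth = border_halfwidth,
                     lad_level = lad_level, ilad_level = ilad_level)
  })
}

#' Simulate a GATC fragment map
#'
#' GATC cut positions are a homogeneous Poisson process with the given mean
#' spacing (~256 bp for random sequence), rather than sequence-derived: Dam
#' methylation is read out at fragment ends, so only the cut positions
#' matter for counting.
#'
#' @param genome A [genome_spec()].
#' @param mean_spacing Mean distance between cuts in bp (default 256).
#' @param seed Integer seed.
#' @return A `gatc_map`: named list of strictly increasing cut positions per
#'   chromosome.
#' @export
make_gatc_map <- function(genome, mean_spacing = 256, seed = 1) {
  if (mean_spacing <= 0) stop("mean_spacing must be positive")
  cuts <- with_substream(seed, "gatc", {
    out <- lapply(seq_len(nrow(genome)), function(i) {
      n <- stats::rpois(1, genome$length[i] / mean_spacing)
      sort(unique(floor(stats::runif(n, 0, genome$length[i]))))
    })
    names(out) <- genome$chrom
    out
  })
  structure(list(cuts = cuts, genome = genome), class = "gatc_map")
}

#' Expected z-score profile under a condition effect
#'
#' Builds the noise-free per-bin expected z track: iLAD baseline plus the
#' LAD elevation smoothed at each border by a logistic transition (borders
#' displaced by `effect$border_shift`, positive = into the iLAD), minus
#' Gaussian dips at CTCF sites and at active genes (FPKM > 1), scaled by
#' `effect$dip_multiplier`, plus any per-LAD offset from
#' `effect$lad_offset_rule`.
#'
#' @param truth A [place_truth()] annotation.
#' @param effect A [condition_effect()]; `NULL` means the unperturbed state.
#' @param bin_size Bin width in bp (default 10 kb).
#' @return A z-score [binned_track()].
#' @export
expected_profile <- function(truth, effect = NULL, bin_size = 1e4) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (is.null(effect)) effect <- condition_effect("baseline")
  # logistic scale from the 25%-75% half-width: plogis runs 0.25->0.75
  # over 2*log(3)*scale
  s <- truth$border_halfwidth / (2 * log(3))
  shift <- effect$border_shift
  genome <- truth$genome
  lens <- genome_lengths(genome)
  offsets <- if (is.null(effect$lad_offset_rule)) {
    rep(0, nrow(truth$lads))
  } else {
    effect$lad_offset_rule(truth$lads)
  }

  values <- lapply(genome$chrom, function(ch) {
    n <- ceiling(lens[[ch]] / bin_size)
    centers <- (seq_len(n) - 0.5) * bin_size
    z <- rep(truth$ilad_level, n)
    lad_idx <- which(truth$lads$chrom == ch)
    for (i in lad_idx) {
      w <- stats::plogis((centers - (truth$lads$start[i] - shift)) / s) *
        stats::plogis(((truth$lads$end[i] + shift) - centers) / s)
      z <- z + (truth$lad_level - truth$ilad_level + offsets[i]) * w
    }
    depth <- truth$dip_depth * effect$dip_multiplier
    if (depth > 0) {
      sites <- truth$ctcf$pos[truth$ctcf$chrom == ch]
      act <- truth$genes[truth$genes$chrom == ch & truth$genes$fpkm > 1, ]
      if (nrow(act) > 0) sites <- c(sites, (act$start + act$end) / 2)
      for (p in sites) {
        z <- z - depth * exp(-(centers - p)^2 / (2 * truth$dip_width^2))
      }
    }
    z
  })
  names(values) <- genome$chrom
  binned_track(values, bin_size, genome, "zscore")
}

#' Simulate pA-DamID read sets
#'
#' Per-bin read counts are negative-binomial with mean proportional to the
#' channel's expected linear signal (`2^(z * z_to_fold)` for the LaminB1
#' channel; flat for the Dam accessibility control unless a Dam profile is
#' supplied); `dispersion = 0` degenerates to Poisson. Each read is placed
#' at a GATC cut position inside its bin; bins containing no cut receive
#' zero reads and are tallied in the `dropped_bins` attribute.
#'
#' @param expected Named list with z-score [binned_track()]s `lamin` and
#'   optionally `dam` (default: flat Dam channel).
#' @param gatc A [make_gatc_map()] fragment map.
#' @param depth Expected total reads per sample (> 0; 0 allowed, giving
#'   empty read sets).
#' @param dispersion Negative-binomial dispersion (variance = mu + disp*mu^2).
#' @param replicates Number of biological replicates per channel.
#' @param seed Integer seed.
#' @param z_to_fold log2 fold change per z unit in the linear signal
#'   (default 1: one z unit is a 2-fold difference).
#' @param sample_prefix Prefix for sample labels.
#' @return List of read sets; each has `sample`, `channel`, `replicate` and
#'   a `records` data.frame (`chrom`, `pos`).
#' @export
simulate_reads <- function(expected, gatc, depth, dispersion = 0.1,
                           replicates = 2, seed = 1, z_to_fold = 1,
                           sample_prefix = "sample") {
  if (depth < 0) stop("depth must be >= 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  lamin <- expected$lamin
  genome <- lamin$genome
  channels <- list(lamin = lamin, dam = expected$dam)

  out <- list()
  for (channel in c("lamin", "dam")) {
    tr <- channels[[channel]]
    # linear expected signal per bin
    lin <- lapply(genome$chrom, function(ch) {
      if (is.null(tr)) {
        rep(1, length(lamin$values[[ch]]))
      } else {
        2^(ifelse(is.na(tr$values[[ch]]), 0, tr$values[[ch]]) * z_to_fold)
      }
    })
    names(lin) <- genome$chrom
    total <- sum(unlist(lin, use.names = FALSE))
    for (rep_i in seq_len(replicates)) {
      stream <- paste0("reads/", channel, "/", rep_i)
      rs <- with_substream(seed, stream, {
        dropped <- 0L
        recs <- lapply(genome$chrom, function(ch) {
          mu <- depth * lin[[ch]] / total
          counts <- if (dispersion == 0) {
            stats::rpois(length(mu), mu)
          } else {
            stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
          }
          cuts <- gatc$cuts[[ch]]
          cut_bin <- bin_index(cuts, lamin$bin_size)
          pos <- vector("list", length(mu))
          for (b in which(counts > 0)) {
            in_bin <- cuts[cut_bin == b]
            if (length(in_bin) == 0L) {
              dropped <<- dropped + 1L
              next
            }
            pos[[b]] <- in_bin[sample.int(length(in_bin), counts[b],
                                          replace = TRUE)]
          }
          p <- unlist(pos, use.names = FALSE)
          if (is.null(p)) p <- numeric(0)
          data.frame(chrom = rep(ch, length(p)), pos = sort(p),
                     stringsAsFactors = FALSE)
        })
        structure(list(sample = sprintf("%s_%s_r%d", sample_prefix, channel,
                                        rep_i),
                       channel = if (channel == "lamin") "LaminB1" else "Dam",
                       replicate = rep_i,
                       records = do.call(rbind, recs)),
                  class = "read_set", dropped_bins = dropped)
      })
      if (attr(rs, "dropped_bins") > 0L) {
        message(rs$sample, ": ", attr(rs, "dropped_bins"),
                " bin(s) without GATC cuts received zero reads")
      }
      out[[rs$sample]] <- rs
    }
  }
  out
}
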