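# shared fixture builders; everything is generated in code, no data files

toy_genome <- function(lengths = c(chr1 = 1e6)) {
  genome_spec(names(lengths), unname(lengths))
}

# binned track from a plain list/vector of values
toy_track <- function(values, bin_size = 1e4, kind = "zscore",
                      genome = NULL) {
  if (!is.list(values)) values <- list(chr1 = values)
  if (is.null(genome)) {
    genome <- genome_spec(names(values), lengths(values) * bin_size)
  }
  binned_track(values, bin_size, genome, kind)
}

# brute-force HMM log-likelihood by full path enumeration (oracle)
bruteforce_loglik <- function(x, model) {
  n <- length(x)
  dens <- function(xt, k) {
    if (is.na(xt)) return(1)
    if (model$emission == "gaussian") {
      dnorm(xt, model$mu[k], model$sigma[k])
    } else {
      dt((xt - model$mu[k]) / model$sigma[k], df = model$df) / model$sigma[k]
    }
  }
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- model$init[s[1]] * dens(x[1], s[1])
    if (n > 1) {
      for (t in 2:n) p <- p * model$trans[s[t - 1], s[t]] * dens(x[t], s[t])
    }
    total <- total + p
  }
  log(total)
}

random_hmm <- function(emission = "gaussian") {
  p <- runif(2, 0.6, 0.99)
  hmm_model(mu = sort(rnorm(2, sd = 2)), sigma = runif(2, 0.3, 2),
            trans = matrix(c(p[1], 1 - p[1], 1 - p[2], p[2]), 2, 2,
                           byrow = TRUE),
            init = {
              a <- runif(1, 0.1, 0.9)
              c(a, 1 - a)
            },
            emission = emission, df = runif(1, 2, 30))
}

# hand-written Benjamini-Hochberg (oracle)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# exact two-sided rank-sum p by enumeration of all group assignments (oracle)
ranksum_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(length(pooled), nx)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  if (w_obs > mu) {
    p <- 2 * mean(w_all >= w_obs)
  } else if (w_obs < mu) {
    p <- 2 * mean(w_all <= w_obs)
  } else {
    p <- 1
  }
  min(p, 1)
}

# two-level truth with sharp borders for recovery experiments
recovery_truth <- function(genome, seed, lad_fraction = 0.4,
                           separation_post_z = 1.6) {
  # raw separation so that the post-z-score separation is the target,
  # given raw within-state noise sd 1:  d / sqrt(1 + d^2 f (1-f)) = target
  f <- lad_fraction
  tz <- separation_post_z
  d <- sqrt(tz^2 / (1 - tz^2 * f * (1 - f)))
  base <- place_truth(genome, lad_fraction = lad_fraction,
                      mean_lad_size = 1e6, ctcf_border_rate = 0,
                      ctcf_intra_rate = 0, gene_rate = 0, dip_depth = 0,
                      seed = seed)
  # snap truth to the 10-kb bin grid so truth is two-level at bin resolution
  lads <- base$lads
  lads$start <- round(lads$start / 1e4) * 1e4
  lads$end <- round(lads$end / 1e4) * 1e4
  lads <- lads[lads$end > lads$start, , drop = FALSE]
  truth_annotation(lads, genome = genome, dip_depth = 0,
                   border_halfwidth = 1e3, # effectively sharp at 10-kb bins
                   lad_level = d * (1 - f), ilad_level = -d * f)
}

# add iid gaussian noise to a track, seeded
noisy_track <- function(expected, sd, seed, kind = "zscore") {
  with_substream(seed, "noise", {
    values <- lapply(expected$values, function(v) v + rnorm(length(v), 0, sd))
    binned_track(values, expected$bin_size, expected$genome, kind)
  })
}

# bin-level LAD indicator for agreement computations
lad_bin_indicator <- function(lads, genome, bin_size) {
  lens <- stats::setNames(genome$length, genome$chrom)
  out <- lapply(genome$chrom, function(ch) {
    n <- ceiling(lens[[ch]] / bin_size)
    v <- logical(n)
    d <- lads[lads$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      a <- floor(d$start[i] / bin_size) + 1
      b <- ceiling(d$end[i] / bin_size)
      v[a:b] <- TRUE
    }
    v
  })
  unlist(out)
}
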