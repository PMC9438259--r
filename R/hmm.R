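#' Construct a two-state HMM
#'
#' Emission distributions are location-scale Gaussian or Student-t (one
#' shared degrees-of-freedom for t, as in robust HMM segmentation of
#' heavy-tailed genomic tracks).
#'
#' @param mu Length-2 emission locations (z units).
#' @param sigma Length-2 emission scales (> 0).
#' @param trans 2x2 row-stochastic transition matrix.
#' @param init Length-2 initial state distribution.
#' @param emission `"gaussian"` or `"t"`.
#' @param df Degrees of freedom (> 0) for t emissions; ignored for Gaussian.
#' @return An `hmm_model` object.
#' @export
hmm_model <- function(mu, sigma, trans, init = c(0.5, 0.5),
                      emission = c("gaussian", "t"), df = 10) {
  emission <- match.arg(emission)
  stopifnot(length(mu) == 2L, length(sigma) == 2L, all(sigma > 0),
            all(dim(trans) == c(2L, 2L)), length(init) == 2L)
  if (any(abs(rowSums(trans) - 1) > 1e-8)) stop("transition rows must sum to 1")
  if (abs(sum(init) - 1) > 1e-8) stop("initial distribution must sum to 1")
  if (emission == "t" && df <= 0) stop("df must be positive")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 trans = trans, init = as.numeric(init),
                 emission = emission,
                 df = if (emission == "t") df else NA_real_),
            class = "hmm_model")
}

# log emission density matrix (T x 2); NA observations (masked bins) get
# log-likelihood 0 (likelihood 1), the standard missing-data treatment
.emission_logdens <- function(x, model) {
  out <- matrix(0, nrow = length(x), ncol = 2L)
  ok <- !is.na(x)
  for (k in 1:2) {
    if (model$emission == "gaussian") {
      out[ok, k] <- stats::dnorm(x[ok], model$mu[k], model$sigma[k], log = TRUE)
    } else {
      z <- (x[ok] - model$mu[k]) / model$sigma[k]
      out[ok, k] <- stats::dt(z, df = model$df, log = TRUE) -
        log(model$sigma[k])
    }
  }
  out
}

# scaled forward pass for one observation vector.
# Returns loglik, and optionally the scaled alpha matrix and log-scale terms.
.forward_chrom <- function(x, model, keep = FALSE) {
  n <- length(x)
  logb <- .emission_logdens(x, model)
  A <- model$trans
  alpha <- matrix(0, n, 2L)
  logc <- numeric(n)
  # shift emissions by their row max so exp() cannot underflow
  shift <- apply(logb, 1, max)
  b <- exp(logb - shift)
  a <- model$init * b[1L, ]
  c1 <- sum(a)
  alpha[1L, ] <- a / c1
  logc[1L] <- log(c1) + shift[1L]
  if (n > 1L) {
    for (t in 2:n) {
      a <- (alpha[t - 1L, ] %*% A)[1L, ] * b[t, ]
      ct <- sum(a)
      alpha[t, ] <- a / ct
      logc[t] <- log(ct) + shift[t]
    }
  }
  res <- list(loglik = sum(logc))
  if (keep) {
    res$alpha <- alpha
    res$b <- b
  }
  res
}

# scaled backward pass matching .forward_chrom's scaling
.backward_chrom <- function(x, model, b) {
  n <- nrow(b)
  A <- model$trans
  beta <- matrix(0, n, 2L)
  beta[n, ] <- 1
  if (n > 1L) {
    for (t in (n - 1L):1L) {
      v <- A %*% (b[t + 1L, ] * beta[t + 1L, ])
      beta[t, ] <- v / sum(v)
    }
  }
  beta
}

#' Log-likelihood of a track under an HMM
#'
#' `log P(observations | model)` by the scaled forward recursion, summed
#' over chromosomes (independent sequences sharing one model). Masked bins
#' contribute emission likelihood 1.
#'
#' @param track A [binned_track()].
#' @param model An [hmm_model()].
#' @return Log-likelihood (numeric scalar).
#' @export
forward_loglik <- function(track, model) {
  sum(vapply(track$values, function(x) .forward_chrom(x, model)$loglik,
             numeric(1)))
}

#' Fit a two-state HMM by Baum-Welch
#'
#' Expectation-maximization on the (replicate-averaged) z-score track, with
#' chromosomes as independent sequences sharing one model. Initialization is
#' deterministic: emission locations at the 25th and 75th percentiles of the
#' unmasked data, scales at the global sd, stay probability 0.99. For t
#' emissions the location/scale updates use the scale-mixture weights and
#' the shared df is re-optimized each iteration (an ECM scheme); every step
#' is monotone in the observed-data log-likelihood.
#'
#' @param track A z-score [binned_track()].
#' @param emission `"t"` (default; robust to heavy tails) or `"gaussian"`.
#' @param tol Convergence tolerance on the log-likelihood improvement.
#' @param max_iter Maximum EM iterations.
#' @param seed Unused for the deterministic initialization; kept so callers
#'   can treat all fitting stages uniformly.
#' @return An [hmm_model()] with attributes `loglik` (per-iteration history)
#'   and `converged`.
#' @export
fit_hmm <- function(track, emission = c("t", "gaussian"), tol = 1e-4,
                    max_iter = 500, seed = 1L) {
  emission <- match.arg(emission)
  xs <- track$values
  all_x <- unlist(xs, use.names = FALSE)
  obs <- all_x[!is.na(all_x)]
  if (length(obs) < 2L) stop("need at least 2 unmasked bins")
  q <- stats::quantile(obs, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] == q[2]) q <- q + c(-1, 1) * 1e-3
  model <- hmm_model(mu = q, sigma = rep(max(stats::sd(obs), 1e-3), 2),
                     trans = matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2,
                                    byrow = TRUE),
                     init = c(0.5, 0.5), emission = emission, df = 10)

  history <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E step, accumulated over chromosomes
    ll <- 0
    g1 <- c(0, 0)            # sum of gamma at t = 1
    xi <- matrix(0, 2, 2)    # expected transition counts
    gsum <- c(0, 0)          # sum of gamma (all t)
    wsum <- c(0, 0)          # sum gamma * u      (u = 1 for gaussian)
    wx <- c(0, 0)            # sum gamma * u * x  (observed bins only)
    gammas <- list()
    for (ci in seq_along(xs)) {
      x <- xs[[ci]]
      fwd <- .forward_chrom(x, model, keep = TRUE)
      ll <- ll + fwd$loglik
      beta <- .backward_chrom(x, model, fwd$b)
      gamma <- fwd$alpha * beta
      gamma <- gamma / rowSums(gamma)
      n <- length(x)
      if (n > 1L) {
        for (t in 1:(n - 1L)) {
          m <- (fwd$alpha[t, ] %o% (fwd$b[t + 1L, ] * beta[t + 1L, ])) *
            model$trans
          xi <- xi + m / sum(m)
        }
      }
      g1 <- g1 + gamma[1L, ]
      gammas[[ci]] <- gamma
    }
    history <- c(history, ll)
    if (iter > 1L && ll - history[iter - 1L] < tol) {
      converged <- TRUE
      break
    }

    # M step
    mu_new <- model$mu
    sigma_new <- model$sigma
    for (k in 1:2) {
      sw <- 0; swx <- 0; sg <- 0; swr <- 0
      for (ci in seq_along(xs)) {
        x <- xs[[ci]]
        ok <- !is.na(x)
        g <- gammas[[ci]][ok, k]
        xo <- x[ok]
        u <- if (model$emission == "t") {
          d <- ((xo - model$mu[k]) / model$sigma[k])^2
          (model$df + 1) / (model$df + d)
        } else rep(1, length(xo))
        sw <- sw + sum(g * u)
        swx <- swx + sum(g * u * xo)
        sg <- sg + sum(g)
      }
      if (sg > 0 && sw > 0) {
        mu_new[k] <- swx / sw
        for (ci in seq_along(xs)) {
          x <- xs[[ci]]
          ok <- !is.na(x)
          g <- gammas[[ci]][ok, k]
          xo <- x[ok]
          u <- if (model$emission == "t") {
            d <- ((xo - model$mu[k]) / model$sigma[k])^2
            (model$df + 1) / (model$df + d)
          } else rep(1, length(xo))
          swr <- swr + sum(g * u * (xo - mu_new[k])^2)
        }
        sigma_new[k] <- max(sqrt(swr / sg), 1e-6)
      }
    }
    trans_new <- xi / pmax(rowSums(xi), .Machine$double.xmin)
    trans_new <- trans_new / rowSums(trans_new)
    init_new <- g1 / sum(g1)

    df_new <- model$df
    if (model$emission == "t") {
      # 1-D maximization of the gamma-weighted observed log density in df;
      # keep the old df unless the optimizer improves on it
      wdens <- function(df) {
        tot <- 0
        for (ci in seq_along(xs)) {
          x <- xs[[ci]]
          ok <- !is.na(x)
          xo <- x[ok]
          for (k in 1:2) {
            z <- (xo - mu_new[k]) / sigma_new[k]
            tot <- tot + sum(gammas[[ci]][ok, k] *
                               (stats::dt(z, df = df, log = TRUE) -
                                  log(sigma_new[k])))
          }
        }
        tot
      }
      opt <- stats::optimize(wdens, interval = c(0.5, 200), maximum = TRUE)
      if (opt$objective > wdens(model$df)) df_new <- opt$maximum
    }

    model <- hmm_model(mu_new, sigma_new, trans_new, init_new,
                       emission = model$emission, df = df_new)
  }
  if (!converged) {
    warning("Baum-Welch did not converge in ", max_iter, " iterations")
  }
  attr(model, "loglik") <- history
  attr(model, "converged") <- converged
  model
}

#' Most probable state path (Viterbi decoding)
#'
#' Decoded per chromosome under the shared model. Ties are broken toward
#' the lower state index. Masked bins contribute emission likelihood 1, so
#' their state is determined by the transition dynamics alone.
#'
#' @param track A [binned_track()].
#' @param model An [hmm_model()].
#' @return Named list of integer state vectors (1 or 2) per chromosome.
#' @export
viterbi_segment <- function(track, model) {
  logA <- log(model$trans)
  out <- lapply(track$values, function(x) {
    n <- length(x)
    logb <- .emission_logdens(x, model)
    delta <- matrix(-Inf, n, 2L)
    psi <- matrix(1L, n, 2L)
    delta[1L, ] <- log(model$init) + logb[1L, ]
    if (n > 1L) {
      for (t in 2:n) {
        for (k in 1:2) {
          cand <- delta[t - 1L, ] + logA[, k]
          psi[t, k] <- which.max(cand) # first max = lower index on ties
          delta[t, k] <- cand[psi[t, k]] + logb[t, k]
        }
      }
    }
    path <- integer(n)
    path[n] <- which.max(delta[n, ])
    if (n > 1L) {
      for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
    }
    path
  })
  names(out) <- names(track$values)
  out
}
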