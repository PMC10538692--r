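# Probabilistic amplitude demodulation (PAD).
#
# Model: y_t = m_t * c_t with a positive slowly varying modulator m and a
# fast carrier c ~ N(0, sigma_c^2) i.i.d. The modulator is m = exp(mu + x)
# where x is a zero-mean stationary Gaussian process whose spectral density
# is a squared-exponential density multiplied by a raised-cosine cutoff at
# `target_rate_hz`, so the log-envelope is band-limited below the target
# rate by construction. Marginalizing nothing, the negative log joint of
# (y, x) given the parameters is
#
#   NL(mu, x) = sum_t [ v_t + y_t^2 exp(-2 v_t) / (2 sigma_c^2) ]
#               + (1/2) x' K^{-1} x,        v = mu + W x,
#
# with W linear interpolation from the latent grid to the signal grid.
# The MAP pair (Bayes' theorem applied to the joint, maximized over
# modulator and carrier) is found by quasi-Newton ascent (L-BFGS-B) in a
# whitened Fourier parameterization x = C^{1/2} a, prior a ~ N(0, I), which
# keeps the problem well conditioned at every cutoff. The carrier is then
# y / m on the signal grid, so the reconstruction identity m * c == y holds
# to machine precision.

#' PAD configuration
#'
#' @param target_rate_hz upper cutoff (Hz) of the modulator's variation:
#'   the timescale constraint of the demodulation round.
#' @param latent_grid_hz sample rate of the latent envelope representation;
#'   must be at least `4 * target_rate_hz` (Nyquist headroom). Default 4x.
#' @param prior_lengthscale_s lengthscale (s) of the squared-exponential
#'   factor of the prior spectrum; default `1 / (2 * pi * target_rate_hz)`.
#' @param prior_variance marginal variance of the latent log-envelope.
#' @param carrier_variance carrier variance `sigma_c^2`.
#' @param max_iterations cap on total quasi-Newton iterations.
#' @param tolerance relative objective change below which iteration stops.
#' @param chunk_s chunk length (s) for long signals; chunks overlap by 1 s
#'   and are cross-faded.
#' @return object of class `pad_config`.
#' @export
pad_config <- function(target_rate_hz,
                       latent_grid_hz = 4 * target_rate_hz,
                       prior_lengthscale_s = 1 / (2 * pi * target_rate_hz),
                       prior_variance = 1,
                       carrier_variance = 1,
                       max_iterations = 300,
                       tolerance = 1e-5,
                       chunk_s = 10) {
  stopifnot(target_rate_hz > 0, latent_grid_hz >= 4 * target_rate_hz,
            prior_variance > 0, carrier_variance > 0,
            max_iterations >= 1, tolerance > 0, chunk_s > 0)
  structure(list(
    target_rate_hz = target_rate_hz,
    latent_grid_hz = latent_grid_hz,
    prior_lengthscale_s = prior_lengthscale_s,
    prior_variance = prior_variance,
    carrier_variance = carrier_variance,
    max_iterations = max_iterations,
    tolerance = tolerance,
    chunk_s = chunk_s
  ), class = "pad_config")
}

# Prior spectral eigenvalues on the n-point circulant latent grid at fl Hz:
# SE spectral density shaped by a raised-cosine cutoff, scaled so that the
# in-band marginal variance equals prior_variance, floored for conditioning.
pad_prior_spectrum <- function(n, fl, cfg) {
  k <- seq(0, n - 1)
  f <- pmin(k, n - k) * fl / n
  S <- exp(-2 * pi^2 * cfg$prior_lengthscale_s^2 * f^2) *
    rc_gain(f, cfg$target_rate_hz)
  S[1] <- 0  # DC carried by the explicit intercept mu
  ms <- mean(S)
  if (ms <= 0) ms <- 1
  S <- S * (cfg$prior_variance / ms)
  pmax(S, 1e-10 * cfg$prior_variance)
}

# Symmetric circulant filter with gain g (length n) applied to real v.
circ_filter <- function(v, g) {
  Re(stats::fft(stats::fft(v) * g, inverse = TRUE)) / length(v)
}

# MAP fit on one chunk. Returns the modulator on the signal grid, the
# latent log-envelope, and the (monotone) log-posterior trace.
pad_fit_chunk <- function(y, rate_hz, cfg) {
  T <- length(y)
  d <- max(1L, floor(rate_hz / cfg$latent_grid_hz))
  fl <- rate_hz / d
  n <- as.integer(ceiling(T / d))
  u <- (seq_len(T) - 1) / d + 1
  i0 <- pmin(floor(u), n); w <- u - i0; i1 <- pmin(i0 + 1L, n)
  up <- function(x) x[i0] * (1 - w) + x[i1] * w
  down <- function(g) {
    r <- rowsum(c(g * (1 - w), g * w), c(i0, i1))
    gx <- numeric(n)
    gx[as.integer(rownames(r))] <- r
    gx
  }

  S <- pad_prior_spectrum(n, fl, cfg)
  sqS <- sqrt(S)
  y2 <- y^2 / cfg$carrier_variance

  nl <- function(par) {
    mu <- par[1]; a <- par[-1]
    v <- mu + up(circ_filter(a, sqS))
    sum(v) + 0.5 * sum(y2 * exp(-2 * v)) + 0.5 * sum(a^2)
  }
  gr <- function(par) {
    mu <- par[1]; a <- par[-1]
    v <- mu + up(circ_filter(a, sqS))
    gv <- 1 - y2 * exp(-2 * v)
    c(sum(gv), circ_filter(down(gv), sqS) + a)
  }

  # Deterministic initialization from the smoothed absolute signal.
  win <- max(1L, round(rate_hz / (2 * cfg$target_rate_hz)))
  sm <- stats::filter(abs(y), rep(1 / win, win), sides = 2)
  sm[is.na(sm)] <- mean(abs(y))
  x0full <- log(as.numeric(sm) + 1e-4)
  x0 <- x0full[pmin((seq_len(n) - 1) * d + 1, T)]
  mu0 <- mean(x0)
  # Regularized inverse of the whitening filter.
  a0 <- circ_filter(x0 - mu0, sqS / (S + 0.01 * max(S)))
  par <- c(mu0, a0)

  inner <- 25L
  trace <- -nl(par)
  converged <- FALSE
  iters <- 0L
  while (iters < cfg$max_iterations) {
    fit <- stats::optim(par, nl, gr, method = "L-BFGS-B",
                        control = list(maxit = inner, factr = 1e7))
    par <- fit$par
    lp <- -fit$value
    prev <- trace[length(trace)]
    trace <- c(trace, lp)
    iters <- iters + inner
    if (abs(lp - prev) <= cfg$tolerance * (abs(prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (fit$convergence == 0 && iters > inner) {
      converged <- TRUE
      break
    }
  }

  mu <- par[1]; a <- par[-1]
  x <- circ_filter(a, sqS)
  list(m_signal = exp(mu + up(x)), x_latent = mu + x,
       latent_rate_hz = fl, decim = d, trace = trace, converged = converged)
}

#' Demodulate a signal into modulator and carrier
#'
#' Returns the MAP modulator/carrier pair under the PAD model. Long signals
#' are processed in overlapping chunks of `config$chunk_s` seconds whose
#' log-envelopes are cross-faded over the 1-s overlaps; the carrier is
#' always the exact residual `y / m`, rescaled to unit variance (with the
#' inverse scale absorbed into the modulator), so `m * c == y` holds to
#' machine precision.
#'
#' @param signal numeric vector, typically z-scored.
#' @param rate_hz sampling rate in Hz.
#' @param config a [pad_config()].
#' @return object of class `demodulation` with elements `modulator` (on the
#'   latent grid), `modulator_signal` (on the signal grid), `carrier`,
#'   `latent_rate_hz`, `reconstruction_error`, `trace` (log-posterior per
#'   outer iteration), and `converged`.
#' @export
pad_demodulate <- function(signal, rate_hz, config) {
  if (any(!is.finite(signal))) stop("non-finite values in signal")
  T <- length(signal)
  if (T < 2 * rate_hz) stop("signal shorter than 2 s")
  y <- signal

  chunk_len <- round(config$chunk_s * rate_hz)
  overlap <- round(1 * rate_hz)
  degenerate <- FALSE

  if (T <= chunk_len * 1.5) {
    starts <- 1L
    ends <- T
  } else {
    step <- chunk_len - overlap
    starts <- seq(1L, T - overlap, by = step)
    ends <- pmin(starts + chunk_len - 1L, T)
    # merge a trailing sliver into the previous chunk
    if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)]) < 2 * rate_hz) {
      ends[length(ends) - 1] <- T
      starts <- starts[-length(starts)]
      ends <- ends[-length(ends)]
    }
  }

  logm <- numeric(T)
  wsum <- numeric(T)
  traces <- list()
  converged <- TRUE
  for (j in seq_along(starts)) {
    idx <- starts[j]:ends[j]
    yc <- y[idx]
    if (sd_pop(yc) < 1e-12) {
      # degenerate chunk: flat modulator at the chunk's mean magnitude
      fit_lm <- rep(log(mean(abs(yc)) + 1e-8), length(idx))
      degenerate <- TRUE
    } else {
      fit <- pad_fit_chunk(yc, rate_hz, config)
      fit_lm <- log(fit$m_signal)
      traces[[length(traces) + 1]] <- fit$trace
      converged <- converged && fit$converged
    }
    wt <- rep(1, length(idx))
    ramp <- min(overlap, length(idx))
    if (j > 1) wt[seq_len(ramp)] <- seq(0, 1, length.out = ramp)
    if (j < length(starts)) wt[length(idx) - seq_len(ramp) + 1] <- seq(0, 1, length.out = ramp)
    logm[idx] <- logm[idx] + wt * fit_lm
    wsum[idx] <- wsum[idx] + wt
  }
  logm <- logm / pmax(wsum, 1e-12)

  m <- exp(logm)
  c_ <- y / m
  s <- stats::sd(c_)
  if (s > 0) { c_ <- c_ / s; m <- m * s }

  d <- max(1L, floor(rate_hz / config$latent_grid_hz))
  lat_idx <- seq(1L, T, by = d)
  if (!converged) warning("PAD optimizer did not converge; returning best iterate")
  structure(list(
    modulator = m[lat_idx],
    modulator_signal = m,
    carrier = c_,
    latent_rate_hz = rate_hz / d,
    reconstruction_error = rel_rms(m * c_, y),
    trace = if (length(traces)) traces[[1]] else numeric(0),
    converged = converged,
    degenerate = degenerate,
    config = config
  ), class = "demodulation")
}

#' @export
print.demodulation <- function(x, ...) {
  cat(sprintf("<demodulation: %d latent pts @ %g Hz, recon err %.2e%s>\n",
              length(x$modulator), x$latent_rate_hz, x$reconstruction_error,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
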