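# Internal helpers shared across modules.

#' Relative root-mean-square difference
#'
#' @param a,b numeric vectors of equal length; `b` is the reference.
#' @return `sqrt(mean((a-b)^2)) / sqrt(mean(b^2))`.
#' @keywords internal
rel_rms <- function(a, b) {
  stopifnot(length(a) == length(b))
  denom <- sqrt(mean(b^2))
  if (denom == 0) return(sqrt(mean((a - b)^2)))
  sqrt(mean((a - b)^2)) / denom
}

# Population (divisor n) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# Deterministic child seed from a parent seed; stays below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103515245 * as.numeric(k)) %% 2147483563) + 1L
}

# Greatest common divisor (integers).
gcd2 <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  abs(a)
}

# Linear upsampling from a latent grid (n points, spacing `d` signal samples,
# first latent point at signal sample 1) to `len` signal samples.
upsample_linear <- function(x, d, len) {
  if (d == 1 && length(x) >= len) return(x[seq_len(len)])
  u <- (seq_len(len) - 1) / d + 1
  i0 <- pmin(floor(u), length(x))
  w <- u - i0
  i1 <- pmin(i0 + 1, length(x))
  x[i0] * (1 - w) + x[i1] * w
}

# Raised-cosine low-pass gain over frequencies `f` (Hz): unity below
# 0.8*cutoff, cosine-squared roll-off to zero at cutoff.
rc_gain <- function(f, cutoff, roll = 0.8) {
  f1 <- roll * cutoff
  g <- numeric(length(f))
  g[f <= f1] <- 1
  tr <- f > f1 & f < cutoff
  g[tr] <- cos(pi / 2 * (f[tr] - f1) / (cutoff - f1))^2
  g
}

# Zero-phase FFT low-pass with mirror padding (avoids wrap-around edge bias).
lowpass_fft <- function(x, rate_hz, cutoff_hz, roll = 0.8) {
  n <- length(x)
  pad <- min(n - 1, ceiling(2 * rate_hz / cutoff_hz))
  xx <- c(rev(x[seq_len(pad) + 1]), x, x[n - seq_len(pad)])
  m <- length(xx)
  f <- abs(seq(0, m - 1) - m * (seq(0, m - 1) > m / 2)) * rate_hz / m
  g <- rc_gain(f, cutoff_hz, roll)
  y <- Re(stats::fft(stats::fft(xx) * g, inverse = TRUE)) / m
  y[pad + seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
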