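# Directed transfer entropy between band envelopes.
#
# T(X -> Y) = H(Y_t | Y_{t-1:t-L}) - H(Y_t | Y_{t-1:t-L}, X_{t-1:t-L}),
# the reduction in uncertainty about the next value of Y from knowing the
# past of X over and above Y's own past. Estimated by the plug-in method:
# both series are discretized into `n_bins` equal-occupancy symbols
# (quantile binning on stable ranks, which makes the estimate invariant to
# strictly monotone transforms of either series), the four joint entropies
# are computed from empirical counts, and negative plug-in noise is clipped
# at zero (the population quantity is nonnegative). Units are bits.

# Equal-occupancy symbolization; ties broken by first-occurrence rank.
quantile_symbols <- function(x, n_bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(x)))
}

# Entropy (bits) of a count vector.
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Integer code of the L-step past of symbol series s (columns t-1 ... t-L).
past_code <- function(s, L, n_bins) {
  n <- length(s)
  idx <- (L + 1):n
  code <- integer(length(idx))
  for (j in seq_len(L)) code <- code * n_bins + (s[idx - j] - 1L)
  code
}

#' Plug-in transfer entropy between two series
#'
#' @param x,y numeric vectors of equal length (source `x`, target `y`), or
#'   already-discretized integer symbol vectors if `discretize = FALSE`.
#' @param history_L history length L (default 1).
#' @param n_bins number of quantile bins (default 4).
#' @param discretize set `FALSE` when `x`, `y` are already integer symbols
#'   in `1..n_bins`.
#' @param clip clip negative plug-in estimates at 0 (default TRUE); the raw
#'   value is returned in the `"raw"` attribute either way.
#' @param warn_length warn when the series is shorter than the recommended
#'   `50 * n_bins^(2L+1)` samples (default TRUE).
#' @return transfer entropy in bits (nonnegative when clipped).
#' @export
transfer_entropy <- function(x, y, history_L = 1, n_bins = 4,
                             discretize = TRUE, clip = TRUE,
                             warn_length = TRUE) {
  stopifnot(length(x) == length(y), history_L >= 1, n_bins >= 2)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in series")
  n <- length(y)
  if (n < 2 * history_L + 1) stop("series shorter than 2L + 1")
  if (sd_pop(x) == 0 || sd_pop(y) == 0) {
    warning("constant series: transfer entropy is 0")
    return(structure(0, raw = 0))
  }
  rec <- 50 * n_bins^(2 * history_L + 1)
  if (warn_length && n < rec) {
    warning("series length ", n, " below recommended ", rec,
            " for ", n_bins, " bins and L = ", history_L)
  }
  sx <- if (discretize) quantile_symbols(x, n_bins) else as.integer(x)
  sy <- if (discretize) quantile_symbols(y, n_bins) else as.integer(y)
  te_symbols(sx, sy, history_L, n_bins, clip)
}

te_symbols <- function(sx, sy, L, n_bins, clip = TRUE) {
  yt <- sy[(L + 1):length(sy)] - 1L
  yp <- past_code(sy, L, n_bins)
  xp <- past_code(sx, L, n_bins)
  BL <- n_bins^L
  h_yp <- entropy_bits(tabulate(yp + 1L, BL))
  h_ytyp <- entropy_bits(tabulate(yt * BL + yp + 1L, n_bins * BL))
  h_ypxp <- entropy_bits(tabulate(yp * BL + xp + 1L, BL * BL))
  h_ytypxp <- entropy_bits(tabulate((yt * BL + yp) * BL + xp + 1L, n_bins * BL * BL))
  raw <- (h_ytyp - h_yp) - (h_ytypxp - h_ypxp)
  structure(if (clip) max(raw, 0) else raw, raw = raw)
}

#' Circular-shift surrogate null for transfer entropy
#'
#' Recomputes the transfer entropy with the source series circularly
#' shifted by seeded random offsets of at least `min_shift` samples (and at
#' most `n - min_shift`), which destroys directed coupling while preserving
#' both marginals and the autocorrelation of each series.
#'
#' @param x,y source and target series.
#' @param n_surrogates number of surrogates (>= 19).
#' @param seed RNG seed.
#' @param history_L,n_bins estimator settings, as in [transfer_entropy()].
#' @param min_shift minimum shift in samples (default: one second at 120 Hz,
#'   i.e. 120 samples, or `n/4` for shorter series).
#' @return list with `mean_bits`, `sd_bits`, `values` (the surrogate TEs).
#' @export
surrogate_null <- function(x, y, n_surrogates = 19, seed = 0,
                           history_L = 1, n_bins = 4, min_shift = NULL) {
  stopifnot(n_surrogates >= 1)
  n <- length(x)
  if (is.null(min_shift)) min_shift <- min(120L, max(2L, n %/% 4))
  if (min_shift >= n - min_shift) min_shift <- max(1L, n %/% 4)
  sx <- quantile_symbols(x, n_bins)
  sy <- quantile_symbols(y, n_bins)
  set.seed(seed)
  shifts <- sample(min_shift:(n - min_shift), n_surrogates, replace = TRUE)
  vals <- vapply(shifts, function(s) {
    xs <- c(sx[(s + 1):n], sx[1:s])
    as.numeric(te_symbols(xs, sy, history_L, n_bins))
  }, numeric(1))
  list(mean_bits = mean(vals), sd_bits = stats::sd(vals), values = vals)
}

#' Directed transfer entropy between hierarchy band pairs
#'
#' Computes both directions of each requested band pair after resampling
#' the envelopes to a common rate by polyphase anti-aliased resampling.
#' Top-down is slower-band source to faster-band target (prosody drives
#' syllable, etc.); bottom-up is the reverse.
#'
#' @param hierarchy an [pad_cascade()] result.
#' @param pairs list of ordered band pairs `(slow, fast)` by band name;
#'   default the three rhythm pairs delta/theta_alpha, delta/beta_gamma,
#'   theta_alpha/beta_gamma.
#' @param te_rate_hz common envelope rate for estimation (default 120 Hz).
#' @param history_L,n_bins estimator settings.
#' @param n_surrogates surrogates per direction (default 19).
#' @param seed seed for the surrogate offsets.
#' @return data frame with one row per pair x direction: `sample_id`,
#'   `pair`, `source_band`, `target_band`, `direction`, `history_L`,
#'   `n_bins`, `te_bits`, `te_raw_bits`, `surrogate_mean_bits`,
#'   `surrogate_sd_bits`.
#' @export
band_pair_te <- function(hierarchy,
                         pairs = list(c("delta", "theta_alpha"),
                                      c("delta", "beta_gamma"),
                                      c("theta_alpha", "beta_gamma")),
                         te_rate_hz = 120, history_L = 1, n_bins = 4,
                         n_surrogates = 19, seed = 0) {
  pair_name <- function(slow, fast) {
    rn <- c(delta = "prosody", theta_alpha = "syllable", beta_gamma = "phoneme")
    paste0(rn[[slow]], "_", rn[[fast]])
  }
  env <- lapply(hierarchy$bands, resample_env,
                from_hz = hierarchy$grid_hz, to_hz = te_rate_hz)
  min_shift <- max(2L, round(te_rate_hz))  # at least 1 s
  rows <- list()
  for (p in pairs) {
    slow <- p[1]; fast <- p[2]
    for (dir in c("top_down", "bottom_up")) {
      src <- if (dir == "top_down") slow else fast
      tgt <- if (dir == "top_down") fast else slow
      te <- transfer_entropy(env[[src]], env[[tgt]], history_L, n_bins,
                             warn_length = FALSE)
      sur <- surrogate_null(env[[src]], env[[tgt]], n_surrogates,
                            seed = derive_seed(seed, length(rows)),
                            history_L = history_L, n_bins = n_bins,
                            min_shift = min_shift)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = hierarchy$source_sample_id,
        pair = pair_name(slow, fast),
        source_band = src, target_band = tgt, direction = dir,
        history_L = history_L, n_bins = n_bins,
        te_bits = as.numeric(te), te_raw_bits = attr(te, "raw"),
        surrogate_mean_bits = sur$mean_bits,
        surrogate_sd_bits = sur$sd_bits,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Polyphase anti-aliased resampling of an envelope between grid rates.
resample_env <- function(x, from_hz, to_hz) {
  if (isTRUE(all.equal(from_hz, to_hz))) return(x)
  # rational approximation of the rate ratio
  p <- round(to_hz * 1000); q <- round(from_hz * 1000)
  g <- gcd2(p, q); p <- p / g; q <- q / g
  as.numeric(signal::resample(x, p, q))
}
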