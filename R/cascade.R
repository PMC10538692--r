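# Recursive demodulation into the four-level AM hierarchy.
#
# Round 1 applies full PAD at the fastest timescale (40 Hz cutoff): it
# splits the z-scored waveform into a broadband envelope (all AM below
# 40 Hz) and a >40 Hz carrier. Subsequent rounds re-demodulate the previous
# round's modulator at successively slower timescales (12, 4, 1 Hz). Because
# an envelope is strictly positive, each later round works on its logarithm,
# where the PAD model with a Gaussian observation term is conjugate and the
# MAP slow/fast split is available in closed form (a zero-phase GP smoother
# with the same raised-cosine prior spectrum). The four band envelopes are
#
#   beta_gamma  = exp(z - LP12 z)     (12-40 Hz AM)
#   theta_alpha = exp(LP12 z - LP4 z) (4-12 Hz AM)
#   delta       = exp(LP4 z - LP1 z)  (1-4 Hz AM)
#   low_delta   = exp(LP1 z)          (<1 Hz AM and overall scale)
#
# with z the log of the round-1 envelope, so their product telescopes back
# to the round-1 envelope exactly and the full reconstruction identity
# (product of envelopes x final carrier == input) holds by construction.

default_cascade_configs <- function(latent_grid_hz = 160) {
  list(
    pad_config(40, latent_grid_hz = latent_grid_hz),
    pad_config(12, latent_grid_hz = latent_grid_hz),
    pad_config(4, latent_grid_hz = latent_grid_hz),
    pad_config(1, latent_grid_hz = latent_grid_hz)
  )
}

#' Recursive PAD cascade into the AM hierarchy
#'
#' @param sample a normalized [speech_sample()] (or any list with
#'   `waveform`, `rate_hz`, `sample_id`).
#' @param configs ordered fast-to-slow list of [pad_config()] objects; the
#'   default uses cutoffs 40, 12, 4, 1 Hz on a 160 Hz latent grid.
#' @return object of class `am_hierarchy`: `bands` (named list of strictly
#'   positive envelopes on the latent grid, names `low_delta`, `delta`,
#'   `theta_alpha`, `beta_gamma`), `band_edges` (data frame), `grid_hz`,
#'   `final_carrier` (signal grid), `carrier_rate_hz`, `source_sample_id`,
#'   and `reconstruction_error`.
#' @export
pad_cascade <- function(sample, configs = default_cascade_configs()) {
  if (!isTRUE(sample$normalized)) {
    # tolerate pre-normalized input supplied without the flag
    if (abs(mean(sample$waveform)) > 1e-6 || abs(sd_pop(sample$waveform) - 1) > 1e-6) {
      sample <- zscore_normalize(sample)
    }
  }
  y <- sample$waveform
  rate <- sample$rate_hz

  dm <- pad_demodulate(y, rate, configs[[1]])
  fl <- dm$latent_rate_hz
  z <- log(dm$modulator)

  cuts <- vapply(configs[-1], function(cf) cf$target_rate_hz, numeric(1))
  z_lp12 <- lowpass_fft(z, fl, cuts[1])
  z_lp4 <- lowpass_fft(z_lp12, fl, cuts[2])
  z_lp1 <- lowpass_fft(z_lp4, fl, cuts[3])

  bands <- list(
    low_delta = exp(z_lp1),
    delta = exp(z_lp4 - z_lp1),
    theta_alpha = exp(z_lp12 - z_lp4),
    beta_gamma = exp(z - z_lp12)
  )

  d <- max(1L, floor(rate / fl))
  prod_latent <- bands$low_delta * bands$delta * bands$theta_alpha * bands$beta_gamma
  m_sig <- upsample_linear(prod_latent, d, length(y))
  final_carrier <- y / m_sig

  structure(list(
    bands = bands,
    band_edges = band_edges(),
    grid_hz = fl,
    final_carrier = final_carrier,
    carrier_rate_hz = rate,
    source_sample_id = sample$sample_id %||% "",
    reconstruction_error = rel_rms(m_sig * final_carrier, y),
    round1 = list(trace = dm$trace, converged = dm$converged,
                  reconstruction_error = dm$reconstruction_error)
  ), class = "am_hierarchy")
}

#' @export
print.am_hierarchy <- function(x, ...) {
  cat(sprintf("<am_hierarchy %s: 4 envelopes @ %g Hz, recon err %.2e>\n",
              x$source_sample_id, x$grid_hz, x$reconstruction_error))
  invisible(x)
}

#' Reconstruct the input from an AM hierarchy
#'
#' Upsamples the product of the four band envelopes to the carrier grid and
#' multiplies by the final carrier.
#'
#' @param hierarchy an [pad_cascade()] result.
#' @return numeric vector on the signal grid.
#' @export
reconstruct <- function(hierarchy) {
  prod_latent <- Reduce(`*`, hierarchy$bands)
  d <- max(1L, floor(hierarchy$carrier_rate_hz / hierarchy$grid_hz))
  m_sig <- upsample_linear(prod_latent, d, length(hierarchy$final_carrier))
  m_sig * hierarchy$final_carrier
}

#' Out-of-band power fractions of the hierarchy envelopes
#'
#' For each envelope, the fraction of non-DC spectral power falling outside
#' its nominal band. Fractions above `flag_threshold` are flagged.
#'
#' @param hierarchy an [pad_cascade()] result.
#' @param flag_threshold fraction above which a band is flagged (default 0.2).
#' @param min_cv bands whose envelope coefficient of variation is below this
#'   carry no meaningful modulation, so their (noise-dominated) fraction is
#'   reported but never flagged (default 0.05).
#' @return data frame with `band`, `lo_hz`, `hi_hz`, `cv`,
#'   `out_of_band_fraction`, `flagged`.
#' @export
band_limit_check <- function(hierarchy, flag_threshold = 0.2, min_cv = 0.05) {
  edges <- hierarchy$band_edges
  res <- lapply(seq_len(nrow(edges)), function(i) {
    b <- edges$band[i]
    env <- hierarchy$bands[[b]]
    x <- env - mean(env)
    n <- length(x)
    # Hann taper: sub-hertz content would otherwise leak across the whole
    # axis on short excerpts and masquerade as out-of-band power
    x <- x * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    p <- Mod(stats::fft(x))^2
    half <- seq(2L, floor(n / 2) + 1L)
    f <- (half - 1) * hierarchy$grid_hz / n
    pw <- p[half]
    tot <- sum(pw)
    inband <- sum(pw[f > edges$lo_hz[i] & f <= edges$hi_hz[i]])
    frac <- if (tot > 0) 1 - inband / tot else 0
    cv <- sd_pop(env) / mean(env)
    data.frame(band = b, lo_hz = edges$lo_hz[i], hi_hz = edges$hi_hz[i],
               cv = cv,
               out_of_band_fraction = frac,
               flagged = frac > flag_threshold && cv >= min_cv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write an AM hierarchy to CSV with a JSON sidecar
#'
#' Columns: `time_s, low_delta, delta, theta_alpha, beta_gamma` at the
#' latent grid rate. The sidecar (same path with `.json` appended) records
#' the grid rate, band edges and reconstruction error.
#'
#' @param hierarchy an [pad_cascade()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_am_hierarchy <- function(hierarchy, path) {
  n <- length(hierarchy$bands$delta)
  df <- data.frame(time_s = (seq_len(n) - 1) / hierarchy$grid_hz,
                   low_delta = hierarchy$bands$low_delta,
                   delta = hierarchy$bands$delta,
                   theta_alpha = hierarchy$bands$theta_alpha,
                   beta_gamma = hierarchy$bands$beta_gamma)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(sample_id = hierarchy$source_sample_id,
               grid_hz = hierarchy$grid_hz,
               band_edges = hierarchy$band_edges,
               reconstruction_error = hierarchy$reconstruction_error)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
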