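# Frequency-domain characterization of the band envelopes.
#
# "Frequency power" of a rhythm is defined as the summed one-sided
# periodogram power of that band's envelope within the band's frequency
# range, after mean removal: no taper, full-length FFT zero-padded to at
# least 0.1 Hz resolution. With this normalization the spectrum satisfies
# Parseval's identity (total one-sided power equals the population variance
# of the mean-removed envelope), so band powers are additive. Content below
# 1 Hz (and DC) is excluded from all band summaries.

rhythm_bands <- function() {
  data.frame(band = c("prosody", "syllable", "phoneme"),
             lo_hz = c(1, 4, 12), hi_hz = c(4, 12, 40),
             stringsAsFactors = FALSE)
}

#' One-sided FFT modulation power spectrum of an envelope
#'
#' @param envelope numeric vector of positive envelope values.
#' @param grid_hz sample rate of the envelope (Hz).
#' @param sample_id,band_name_of_source identifiers carried through to the
#'   output.
#' @param resolution_hz maximum frequency-grid spacing; the FFT is
#'   zero-padded until the spacing is at most this (default 0.1 Hz).
#' @param min_duration_s validation threshold: envelopes shorter than this
#'   are rejected (default 10 s, the corpus inclusion rule). Set lower for
#'   short diagnostic fixtures.
#' @return object of class `modulation_spectrum`: `freqs_hz`, `power`
#'   (one-sided, summing to the envelope's population variance),
#'   `band_power` (named: prosody, syllable, phoneme), `sample_id`,
#'   `band_name_of_source`, `grid_hz`.
#' @export
modulation_spectrum <- function(envelope, grid_hz, sample_id = "",
                                band_name_of_source = "broadband",
                                resolution_hz = 0.1, min_duration_s = 10) {
  n <- length(envelope)
  if (n < min_duration_s * grid_hz) {
    stop("envelope shorter than ", min_duration_s, " s at ", grid_hz, " Hz")
  }
  x <- envelope - mean(envelope)
  nfft <- stats::nextn(max(n, ceiling(grid_hz / resolution_hz)), 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  p2 <- Mod(X)^2 / (nfft * n)          # two-sided; sums to population variance
  half <- floor(nfft / 2)
  pow <- p2[seq_len(half + 1)]
  dbl <- 2:(half + if (nfft %% 2 == 0) 0 else 1)
  pow[dbl] <- 2 * pow[dbl]
  freqs <- (0:half) * grid_hz / nfft

  bp <- band_power_from_spectrum(freqs, pow)
  structure(list(freqs_hz = freqs, power = pow, band_power = bp,
                 sample_id = sample_id,
                 band_name_of_source = band_name_of_source,
                 grid_hz = grid_hz, n = n),
            class = "modulation_spectrum")
}

band_power_from_spectrum <- function(freqs, power) {
  rb <- rhythm_bands()
  bp <- vapply(seq_len(nrow(rb)), function(i) {
    sum(power[freqs > rb$lo_hz[i] & freqs <= rb$hi_hz[i]])
  }, numeric(1))
  names(bp) <- rb$band
  bp
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat(sprintf("<modulation_spectrum %s/%s: %d bins to %.1f Hz; prosody %.3g, syllable %.3g, phoneme %.3g>\n",
              x$sample_id, x$band_name_of_source, length(x$freqs_hz),
              max(x$freqs_hz), x$band_power["prosody"],
              x$band_power["syllable"], x$band_power["phoneme"]))
  invisible(x)
}

#' Average modulation spectra within groups
#'
#' Spectra are re-gridded onto the first spectrum's frequency axis by
#' linear interpolation when axes differ, then averaged pointwise within
#' each direction label; band powers are averaged likewise.
#'
#' @param spectra list of [modulation_spectrum()] objects.
#' @param grouping named character vector mapping `sample_id` to a
#'   direction label.
#' @return named list (one entry per non-empty group) of
#'   `modulation_spectrum` objects with an added `n_samples` field.
#' @export
group_average_spectra <- function(spectra, grouping) {
  if (!length(spectra)) return(list())
  ref <- spectra[[1]]$freqs_hz
  labels <- vapply(spectra, function(s) unname(grouping[s$sample_id]), character(1))
  if (anyNA(labels)) stop("sample_id missing from grouping: ",
                          paste(unique(vapply(spectra, function(s) s$sample_id,
                                              character(1))[is.na(labels)]), collapse = ", "))
  out <- list()
  for (g in unique(labels)) {
    members <- spectra[labels == g]
    if (!length(members)) { warning("empty group ", g, " excluded"); next }
    mats <- vapply(members, function(s) {
      if (identical(s$freqs_hz, ref)) s$power
      else stats::approx(s$freqs_hz, s$power, ref, rule = 2)$y
    }, numeric(length(ref)))
    bps <- vapply(members, function(s) s$band_power, numeric(3))
    avg <- structure(list(
      freqs_hz = ref,
      power = rowMeans(mats),
      band_power = rowMeans(bps),
      sample_id = paste0("mean:", g),
      band_name_of_source = members[[1]]$band_name_of_source,
      grid_hz = members[[1]]$grid_hz,
      n_samples = length(members)
    ), class = "modulation_spectrum")
    out[[g]] <- avg
  }
  out
}

# Analytic Morlet CWT magnitude of a real series via FFT.
cwt_morlet <- function(x, rate_hz, freqs_hz, omega0 = 6) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x - mean(x), numeric(nfft - n)))
  wk <- 2 * pi * seq(0, nfft - 1) / nfft   # angular frequency per sample
  pos <- wk <= pi
  out <- matrix(0, nrow = length(freqs_hz), ncol = n)
  for (i in seq_along(freqs_hz)) {
    s <- omega0 / (2 * pi * freqs_hz[i] / rate_hz)
    H <- numeric(nfft)
    H[pos] <- exp(-0.5 * (s * wk[pos] - omega0)^2)
    W <- stats::fft(X * H, inverse = TRUE) / nfft
    out[i, ] <- Mod(W[seq_len(n)])
  }
  out
}

#' Continuous-wavelet scalogram of an envelope
#'
#' Analytic Morlet magnitude over 0.1-40 Hz on a logarithmic scale axis,
#' in dB with the maximum normalized to 0 dB. When the envelope is longer
#' than `window_s`, a `window_s`-second excerpt is chosen by a seeded RNG,
#' so the same seed always selects the same excerpt.
#'
#' @param envelope numeric vector of envelope values.
#' @param grid_hz envelope sample rate (Hz).
#' @param window_s excerpt length in seconds (default 4).
#' @param seed RNG seed for excerpt selection (default 0).
#' @param n_freqs number of scales (default 96).
#' @param freq_range two-element range of modulation rates in Hz.
#' @return object of class `scalogram`: `times_s`, `scales_hz`,
#'   `magnitude_db` (scales x times, max 0 dB), `excerpt_start_s`.
#' @export
scalogram <- function(envelope, grid_hz, window_s = 4, seed = 0,
                      n_freqs = 96, freq_range = c(0.1, 40)) {
  win <- round(window_s * grid_hz)
  if (length(envelope) < win) stop("envelope shorter than the scalogram window")
  start <- 1L
  if (length(envelope) > win) {
    set.seed(seed)
    start <- sample.int(length(envelope) - win + 1L, 1L)
  }
  x <- envelope[start:(start + win - 1L)]
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_freqs))
  mag <- cwt_morlet(x, grid_hz, freqs)
  mx <- max(mag)
  db <- 20 * log10(pmax(mag, mx * 1e-8) / mx)
  structure(list(times_s = (seq_len(win) - 1) / grid_hz,
                 scales_hz = freqs,
                 magnitude_db = db,
                 excerpt_start_s = (start - 1) / grid_hz),
            class = "scalogram")
}

#' Plot a scalogram
#'
#' @param x a [scalogram()].
#' @param main plot title.
#' @param ... further arguments to [graphics::image()].
#' @export
plot.scalogram <- function(x, main = "", ...) {
  graphics::image(x$times_s, x$scales_hz, t(x$magnitude_db),
                  log = "y", xlab = "time (s)", ylab = "modulation rate (Hz)",
                  main = main, col = grDevices::hcl.colors(64, "Inferno"), ...)
  invisible(x)
}

#' Write a scalogram to PNG and its magnitude matrix to CSV
#'
#' @param sc a [scalogram()].
#' @param png_path output PNG path (skipped if NULL).
#' @param csv_path output CSV path for the dB matrix, first column
#'   `scale_hz`, remaining columns one per time point (skipped if NULL).
#' @param main plot title.
#' @return `png_path`, invisibly.
#' @export
write_scalogram <- function(sc, png_path = NULL, csv_path = NULL, main = "") {
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 700, height = 450)
    plot(sc, main = main)
    grDevices::dev.off()
  }
  if (!is.null(csv_path)) {
    df <- cbind(data.frame(scale_hz = sc$scales_hz),
                as.data.frame(sc$magnitude_db))
    names(df)[-1] <- sprintf("t%.4f", sc$times_s)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(png_path)
}

#' Tidy per-sample band-power table from a hierarchy
#'
#' Computes each rhythm's "frequency power" as the band power of that
#' band's own envelope (prosody from the delta envelope, syllable from
#' theta-alpha, phoneme from beta-gamma). As a cross-check the delta-,
#' theta- and beta-band powers of the broadband (round-1) product envelope
#' can be obtained by passing the product envelope to
#' [modulation_spectrum()] directly.
#'
#' @param hierarchy an [pad_cascade()] result.
#' @param min_duration_s forwarded to [modulation_spectrum()].
#' @return one-row data frame: `sample_id`, `prosody_power`,
#'   `syllable_power`, `phoneme_power`.
#' @export
hierarchy_band_powers <- function(hierarchy, min_duration_s = 10) {
  src <- c(prosody = "delta", syllable = "theta_alpha", phoneme = "beta_gamma")
  pw <- vapply(names(src), function(rh) {
    sp <- modulation_spectrum(hierarchy$bands[[src[[rh]]]], hierarchy$grid_hz,
                              sample_id = hierarchy$source_sample_id,
                              band_name_of_source = src[[rh]],
                              min_duration_s = min_duration_s)
    sp$band_power[[rh]]
  }, numeric(1))
  data.frame(sample_id = hierarchy$source_sample_id,
             prosody_power = pw[["prosody"]],
             syllable_power = pw[["syllable"]],
             phoneme_power = pw[["phoneme"]],
             stringsAsFactors = FALSE)
}
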