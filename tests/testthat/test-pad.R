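# Demodulation properties: identity, monotone objective, scale covariance,
# timescale constraint, recovery against generator ground truth.

test_that("modulator of constant-amplitude white noise is nearly flat", {
  set.seed(11)
  y <- rnorm(10000); y <- (y - mean(y)) / sd(y)
  dm <- pad_demodulate(y, 1000, pad_config(4, latent_grid_hz = 16))
  cv <- sd(dm$modulator) / mean(dm$modulator)
  expect_lt(cv, 0.1)
  expect_true(all(dm$modulator > 0))
  # carrier is approximately the (scaled) input
  expect_gt(cor(dm$carrier, y), 0.99)
})

test_that("a 2 Hz amplitude envelope is recovered with r >= 0.9", {
  fx <- am_noise_signal(duration_s = 10, rate_hz = 1000, f = 2, depth = 0.9,
                        seed = 21)
  dm <- pad_demodulate(fx$y, fx$rate_hz, pad_config(4, latent_grid_hz = 16))
  expect_gte(cor(dm$modulator_signal, fx$env), 0.9)
  expect_lt(dm$reconstruction_error, 1e-6)
  expect_equal(sd(dm$carrier), 1, tolerance = 0.15)
})

test_that("amplitude modulation faster than the cutoff is relegated to the carrier", {
  fx <- am_noise_signal(duration_s = 10, rate_hz = 1000, f = 8, depth = 0.8,
                        seed = 5)
  dm <- pad_demodulate(fx$y, fx$rate_hz, pad_config(4, latent_grid_hz = 32))
  m <- dm$modulator - mean(dm$modulator)
  n <- length(m)
  p <- Mod(fft(m))^2
  half <- 2:floor(n / 2)
  f <- (half - 1) * dm$latent_rate_hz / n
  frac_above <- sum(p[half][f > 4]) / sum(p[half])
  expect_lt(frac_above, 0.05)
})

test_that("log-posterior trace is non-decreasing and the fit is deterministic", {
  fx <- am_noise_signal(seed = 31)
  cfg <- pad_config(4, latent_grid_hz = 16)
  dm1 <- pad_demodulate(fx$y, fx$rate_hz, cfg)
  expect_true(all(diff(dm1$trace) >= -1e-8 * abs(dm1$trace[-length(dm1$trace)])))
  dm2 <- pad_demodulate(fx$y, fx$rate_hz, cfg)
  expect_identical(dm1$modulator, dm2$modulator)
})

test_that("demodulation is scale-covariant: a*y gives a*m and the same carrier", {
  fx <- am_noise_signal(seed = 41)
  cfg <- pad_config(4, latent_grid_hz = 16)
  dm1 <- pad_demodulate(fx$y, fx$rate_hz, cfg)
  dm2 <- pad_demodulate(5 * fx$y, fx$rate_hz, cfg)
  expect_equal(dm2$modulator_signal / dm1$modulator_signal,
               rep(5, length(dm1$modulator_signal)), tolerance = 0.02)
  expect_gt(cor(dm1$carrier, dm2$carrier), 0.9999)
})

test_that("PAD modulator agrees with the low-passed Hilbert magnitude envelope", {
  # independent oracle: for a band-limited envelope and white carrier the
  # analytic-signal magnitude, low-passed, approximates the true envelope
  fx <- am_noise_signal(duration_s = 10, rate_hz = 1000, f = 1.5, depth = 0.7,
                        seed = 51)
  n <- length(fx$y)
  X <- fft(fx$y)
  h <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  hil <- Mod(fft(X * h, inverse = TRUE) / n)
  oracle <- speechrhythm:::lowpass_fft(hil, 1000, 4)
  dm <- pad_demodulate(fx$y, 1000, pad_config(4, latent_grid_hz = 16))
  expect_gte(cor(dm$modulator_signal, oracle), 0.95)
})

test_that("parameter recovery holds across seeds of the generative model", {
  # known GP-lengthscale exponential-link generative model: log-envelope is
  # band-limited noise; median recovery correlation over seeds >= 0.9
  rs <- vapply(1:8, function(seed) {
    set.seed(seed)
    rate <- 1000
    n <- 10 * rate
    x <- speechrhythm:::lowpass_fft(rnorm(n), rate, 3) * 3
    env <- exp(x - mean(x))
    y <- env * rnorm(n)
    y <- (y - mean(y)) / sd(y)
    dm <- pad_demodulate(y, rate, pad_config(4, latent_grid_hz = 16))
    cor(dm$modulator_signal, env)
  }, numeric(1))
  expect_gte(median(rs), 0.9)
})

test_that("chunked processing of long signals stays accurate at the seams", {
  fx <- am_noise_signal(duration_s = 25, rate_hz = 1000, f = 2, depth = 0.8,
                        seed = 61)
  cfg <- pad_config(4, latent_grid_hz = 16, chunk_s = 10)
  dm <- pad_demodulate(fx$y, fx$rate_hz, cfg)
  expect_gte(cor(dm$modulator_signal, fx$env), 0.9)
  expect_lt(dm$reconstruction_error, 1e-6)
})

test_that("invalid inputs are rejected", {
  expect_error(pad_demodulate(c(1, NA, 3), 10, pad_config(1)), "non-finite")
  expect_error(pad_demodulate(rnorm(100), 1000, pad_config(4)), "shorter than 2 s")
  expect_error(pad_config(4, latent_grid_hz = 8), "latent_grid_hz")
})

test_that("cascade envelopes are positive, band-limited and reconstruct the input", {
  sy <- quick_sample(seed = 71)
  h <- pad_cascade(sy$sample)
  expect_true(all(vapply(h$bands, function(b) all(b > 0), logical(1))))
  expect_equal(h$band_edges$lo_hz, c(0, 1, 4, 12))
  expect_equal(h$band_edges$hi_hz, c(1, 4, 12, 40))
  expect_lt(h$reconstruction_error, 1e-3)
  y2 <- reconstruct(h)
  z <- zscore_normalize(sy$sample)$waveform
  expect_lt(speechrhythm:::rel_rms(y2, z), 1e-3)
  chk <- band_limit_check(h)
  expect_false(any(chk$flagged))
})

test_that("cascade recovers each nested ground-truth envelope", {
  sy <- quick_sample(seed = 81)
  h <- pad_cascade(sy$sample)
  for (b in c("delta", "theta_alpha", "beta_gamma")) {
    expect_gte(envelope_recovery(h, sy, b), 0.8)
  }
})

test_that("cascade of a pure noise carrier has nearly flat envelopes", {
  set.seed(91)
  s <- speech_sample("flat", rnorm(10 * 2000), 2000, "respondent", "NT")
  h <- pad_cascade(zscore_normalize(s))
  for (b in c("delta", "theta_alpha", "beta_gamma")) {
    cv <- sd(h$bands[[b]]) / mean(h$bands[[b]])
    expect_lt(cv, 0.12)
  }
})

test_that("band_limit_check flags out-of-band tones", {
  t <- seq_len(1600) / 160
  h <- list(bands = list(low_delta = rep(1, 1600),
                         delta = 1 + 0.5 * sin(2 * pi * 2 * t),
                         theta_alpha = 1 + 0.5 * sin(2 * pi * 6 * t),
                         beta_gamma = 1 + 0.5 * sin(2 * pi * 20 * t)),
            band_edges = speechrhythm:::band_edges(), grid_hz = 160)
  class(h) <- "am_hierarchy"
  chk <- band_limit_check(h)
  expect_false(any(chk$flagged))
  expect_lt(chk$out_of_band_fraction[chk$band == "delta"], 0.01)
  # a 20 Hz tone in the delta slot is flagged
  h$bands$delta <- 1 + 0.5 * sin(2 * pi * 20 * t)
  chk2 <- band_limit_check(h)
  expect_true(chk2$flagged[chk2$band == "delta"])
  expect_gt(chk2$out_of_band_fraction[chk2$band == "delta"], 0.99)
})

test_that("hierarchy CSV export round-trips the envelopes", {
  sy <- quick_sample(seed = 101)
  h <- pad_cascade(sy$sample)
  f <- tempfile(fileext = ".csv")
  write_am_hierarchy(h, f)
  df <- read.csv(f)
  expect_equal(df$delta, h$bands$delta, tolerance = 1e-12)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$grid_hz, h$grid_hz)
})
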