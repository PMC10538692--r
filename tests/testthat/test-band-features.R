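# Modulation spectra: Parseval, frequency-axis correctness, band powers,
# group averaging; scalogram determinism and ridge location.

tone_env <- function(f, grid_hz = 120, duration_s = 10, depth = 0.5) {
  t <- seq_len(duration_s * grid_hz) / grid_hz
  1 + depth * sin(2 * pi * f * t)
}

test_that("a 2 Hz AM tone peaks at 2 Hz with >99% of non-DC power in the prosody band", {
  env <- tone_env(2)
  sp <- modulation_spectrum(env, 120)
  pk <- sp$freqs_hz[which.max(sp$power[-1]) + 1]
  step <- diff(sp$freqs_hz[1:2])
  expect_lt(abs(pk - 2), step + 1e-9)
  expect_gt(sp$band_power[["prosody"]] / sum(sp$power[-1]), 0.99)
})

test_that("Parseval holds: total one-sided power equals the population variance", {
  for (seed in 1:3) {
    set.seed(seed)
    env <- abs(1 + cumsum(rnorm(1500)) / 50)
    sp <- modulation_spectrum(env, 120)
    v <- mean((env - mean(env))^2)
    expect_equal(sum(sp$power), v, tolerance = 1e-6)
  }
})

test_that("frequency axis is correct for tones at 2, 6 and 20 Hz", {
  for (f in c(2, 6, 20)) {
    sp <- modulation_spectrum(tone_env(f), 120)
    pk <- sp$freqs_hz[which.max(sp$power[-1]) + 1]
    step <- diff(sp$freqs_hz[1:2])
    expect_lt(abs(pk - f), step + 1e-9)
    band <- c(`2` = "prosody", `6` = "syllable", `20` = "phoneme")[[as.character(f)]]
    expect_gt(sp$band_power[[band]] / sum(sp$power[-1]), 0.99)
  }
})

test_that("constant envelope has an all-zero spectrum and zero band powers", {
  sp <- modulation_spectrum(rep(2.5, 1200), 120)
  expect_true(all(sp$power == 0))
  expect_true(all(sp$band_power == 0))
})

test_that("short envelopes are rejected; band indices are attached", {
  expect_error(modulation_spectrum(rep(1, 100), 120), "shorter")
  sp <- modulation_spectrum(tone_env(2), 120)
  expect_named(sp$band_power, c("prosody", "syllable", "phoneme"))
})

test_that("group averaging is pointwise, permutation-invariant, and drops empty groups", {
  sps <- lapply(1:4, function(i) {
    modulation_spectrum(tone_env(2, depth = 0.2 * i), 120,
                        sample_id = paste0("s", i))
  })
  grouping <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  avg <- group_average_spectra(sps, grouping)
  expect_named(avg, c("A", "B"))
  expect_equal(avg$A$power, (sps[[1]]$power + sps[[2]]$power) / 2)
  expect_equal(avg$A$n_samples, 2)
  # identical inputs average to themselves
  avg2 <- group_average_spectra(list(sps[[1]], sps[[1]]), c(s1 = "A"))
  expect_equal(avg2$A$power, sps[[1]]$power)
  # permutation invariance
  avg3 <- group_average_spectra(rev(sps), grouping)
  expect_equal(avg3$A$power, avg$A$power)
})

test_that("weak-prosody group has lower mean prosody band power", {
  sps <- c(lapply(1:3, function(i) modulation_spectrum(tone_env(2, depth = 0.7),
                                                       120, sample_id = paste0("w", i))),
           lapply(1:3, function(i) modulation_spectrum(tone_env(2, depth = 0.2),
                                                       120, sample_id = paste0("k", i))))
  grouping <- c(w1 = "strong", w2 = "strong", w3 = "strong",
                k1 = "weak", k2 = "weak", k3 = "weak")
  avg <- group_average_spectra(sps, grouping)
  expect_lt(avg$weak$band_power[["prosody"]], avg$strong$band_power[["prosody"]])
})

test_that("scalogram shows a ridge at the AM rate and is seed-deterministic", {
  env <- tone_env(2, grid_hz = 160, duration_s = 10)
  sc1 <- scalogram(env, 160, seed = 7)
  expect_equal(max(sc1$magnitude_db), 0)
  ridge <- sc1$scales_hz[apply(sc1$magnitude_db, 2, which.max)]
  expect_lt(abs(median(ridge) - 2), 0.4)
  sc2 <- scalogram(env, 160, seed = 7)
  expect_identical(sc1$magnitude_db, sc2$magnitude_db)
  expect_identical(sc1$excerpt_start_s, sc2$excerpt_start_s)
  sc3 <- scalogram(env, 160, seed = 8)
  expect_false(identical(sc3$excerpt_start_s, sc1$excerpt_start_s))
})

test_that("scalograms separate strong- from weak-prosody synthetic speech below 5 Hz", {
  mk <- function(depth, kappa, seed) {
    sy <- synth_generate(synth_spec(duration_s = 10, rate_hz = 2000,
                                    prosody = c(2, depth),
                                    coupling_kappa = kappa, seed = seed))
    h <- pad_cascade(sy$sample)
    env <- h$bands$low_delta * h$bands$delta * h$bands$theta_alpha * h$bands$beta_gamma
    scalogram(env, h$grid_hz, seed = 1)
  }
  sc_nt <- mk(0.8, 0.7, 111)
  sc_aut <- mk(0.1, 0.1, 112)
  low <- function(sc) {
    sel <- sc$scales_hz < 5 & sc$scales_hz > 1
    mean(sc$magnitude_db[sel, ])
  }
  # low-frequency structure visible (closer to the 0 dB max) for strong
  # prosody, attenuated for weak prosody
  expect_gt(low(sc_nt), low(sc_aut) + 3)
})

test_that("hierarchy band powers come from each band's own envelope", {
  sy <- quick_sample(seed = 121)
  h <- pad_cascade(sy$sample)
  bp <- hierarchy_band_powers(h)
  sp_d <- modulation_spectrum(h$bands$delta, h$grid_hz)
  expect_equal(bp$prosody_power, sp_d$band_power[["prosody"]])
  expect_true(all(c(bp$prosody_power, bp$syllable_power, bp$phoneme_power) >= 0))
})
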