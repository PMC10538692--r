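# Generator contracts: determinism, positivity, exact reconstruction,
# spectral placement of the truth envelopes, cohort structure.

test_that("same spec and seed give bit-identical waveforms; different seeds decorrelate", {
  sp <- synth_spec(duration_s = 10, seed = 42)
  s1 <- synth_generate(sp)
  s2 <- synth_generate(sp)
  expect_identical(s1$sample$waveform, s2$sample$waveform)
  s3 <- synth_generate(synth_spec(duration_s = 10, seed = 43))
  expect_lt(abs(cor(s1$sample$waveform, s3$sample$waveform)), 0.05)
})

test_that("zero depths give a pure carrier with constant truth envelopes", {
  sp <- synth_spec(duration_s = 10, prosody = c(2, 0), syllable = c(6, 0),
                   phoneme = c(20, 0), seed = 7)
  sy <- synth_generate(sp)
  expect_true(all(sy$truth$delta == 1))
  expect_true(all(sy$truth$theta_alpha == 1))
  expect_true(all(sy$truth$beta_gamma == 1))
  expect_equal(synth_reconstruct(sy), sy$carrier)
})

test_that("truth envelopes are strictly positive and depth >= 1 is rejected", {
  sy <- quick_sample(seed = 8)
  expect_true(all(vapply(sy$truth, function(e) all(e > 0), logical(1))))
  expect_error(synth_spec(prosody = c(2, 1)), "depth")
  expect_error(synth_spec(prosody = c(0.5, 0.5)), "rate")
})

test_that("product of truth envelopes times carrier equals the pre-noise waveform", {
  sy <- quick_sample(seed = 9)
  pre <- synth_reconstruct(sy)
  resid <- sy$sample$waveform - pre
  # the residual is exactly the additive noise at the requested SNR
  snr_emp <- 10 * log10(mean(pre^2) / mean(resid^2))
  expect_equal(snr_emp, sy$spec$snr_db, tolerance = 1)
})

test_that("delta truth envelope concentrates >95% of non-DC power in 1-4 Hz", {
  sy <- synth_generate(synth_spec(duration_s = 10, prosody = c(2, 0.8),
                                  syllable = c(6, 0.6), phoneme = c(20, 0.4),
                                  coupling_kappa = 0.8, seed = 10))
  sp <- modulation_spectrum(sy$truth$delta, sy$truth_grid_hz)
  expect_gt(sp$band_power[["prosody"]] / sum(sp$power[-1]), 0.95)
})

test_that("power-normalized coupling leaves syllable band power kappa-independent", {
  pow <- function(kappa, seed) {
    sy <- synth_generate(synth_spec(duration_s = 20, coupling_kappa = kappa,
                                    seed = seed), audio = FALSE)
    sp <- modulation_spectrum(sy$truth$theta_alpha, sy$truth_grid_hz)
    sp$band_power[["syllable"]]
  }
  p0 <- mean(vapply(1:10, function(s) pow(0, s), numeric(1)))
  p8 <- mean(vapply(1:10, function(s) pow(0.8, s + 100), numeric(1)))
  expect_equal(p8 / p0, 1, tolerance = 0.1)
})

test_that("cohort has four groups, dyadic structure, and the designed power ordering", {
  co <- generate_cohort(30, seed = 1, audio = FALSE)
  man <- co$manifest
  expect_equal(nrow(man), 120)
  counts <- table(man$direction_label)[c("AUT_speech", "NT_speech",
                                         "AUT_directed", "NT_directed")]
  expect_equal(as.vector(counts), rep(30L, 4))
  # one questioner identity per dyad
  q <- man[man$role == "questioner", ]
  expect_true(all(tapply(q$speaker_id, q$dyad_id,
                         function(s) length(unique(s))) == 1))
  # group mean prosody truth power lower in AUT-like groups
  pw <- vapply(co$samples, function(s) {
    sp <- modulation_spectrum(s$truth$delta, s$truth_grid_hz)
    sp$band_power[["prosody"]]
  }, numeric(1))
  agg <- tapply(pw, man$direction_label, mean)
  expect_lt(agg[["AUT_speech"]], agg[["NT_speech"]])
  expect_lt(agg[["AUT_directed"]], agg[["NT_directed"]])
  # durations within the sampled range
  expect_true(all(man$duration_s >= 10 & man$duration_s <= 30))
})

test_that("beta = 0 override removes the dyadic depth correlation", {
  rs <- vapply(1:20, function(s) {
    co <- generate_cohort(14, seed = s, audio = FALSE,
                          preset_overrides = list(dyad_beta = 0, dyad_alpha = 0.45,
                                                  dyad_noise_sd = 0.15))
    man <- co$manifest
    d <- unique(man[, c("dyad_id", "role", "prosody_depth")])
    qd <- tapply(man$prosody_depth[man$role == "questioner"],
                 man$dyad_id[man$role == "questioner"], mean)
    rd <- tapply(man$prosody_depth[man$role == "respondent"],
                 man$dyad_id[man$role == "respondent"], mean)
    common <- intersect(names(qd), names(rd))
    cor(qd[common], rd[common], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("short duration draws are excluded by the inclusion filter at the stated count", {
  co <- generate_cohort(10, seed = 3,
                        preset_overrides = list(duration_range = c(6, 14),
                                                rate_hz = 500))
  samples <- lapply(co$samples, `[[`, "sample")
  kept <- filter_samples(samples, 10)
  expect_equal(length(kept), sum(co$manifest$duration_s >= 10))
  expect_lt(length(kept), length(samples))
})

test_that("cohort WAV export writes the manifest dialect read_manifest accepts", {
  co <- generate_cohort(2, seed = 4,
                        preset_overrides = list(duration_range = c(10, 11),
                                                rate_hz = 8000))
  dir <- file.path(tempdir(), "cohort_export")
  path <- write_cohort(co, dir)
  man <- read_manifest(path)
  expect_equal(nrow(man), 8)
  s <- load_sample(man$file[1], man[1, ])
  expect_equal(s$rate_hz, 8000)
  expect_equal(s$duration_s, co$manifest$duration_s[1], tolerance = 0.01)
  unlink(dir, recursive = TRUE)
})
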