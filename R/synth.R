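# Synthetic nested-AM signal generation.
#
# A speech-like signal is built as a product of three positive band
# envelopes riding on a fast carrier:
#
#   y(t) = [1 + d_p s_p(t)] * [1 + d_s(t) s_s(t)] * [1 + d_f(t) s_f(t)] * c(t) + noise
#
# where s_p, s_s, s_f are unit-amplitude jittered oscillations at the
# prosodic (1-4 Hz), syllabic (4-12 Hz) and phonetic (12-40 Hz) rates, and
# c(t) is a >40 Hz carrier. Cross-band coupling with strength kappa gates
# the syllabic depth by the prosodic phase (and the phonetic depth by the
# syllabic phase) through the power-normalized gate
#
#   d_s(t) = d_s * (1 + (kappa/2) s_p(t)) / sqrt(1 + kappa^2 / 8),
#
# a directed slow->fast dependence whose normalization keeps the marginal
# band power independent of kappa, so coupling strength and per-band
# modulation depth are controlled separately. Envelopes are generated on
# the latent grid (default 160 Hz) and upsampled linearly to the signal
# rate; the stored ground-truth envelopes are the latent versions, and
# [synth_reconstruct()] rebuilds the pre-noise waveform from them exactly.

#' Specification of one synthetic nested-AM signal
#'
#' @param duration_s signal length in seconds.
#' @param rate_hz sampling rate (default 2000 Hz: ample headroom for a
#'   >40 Hz carrier while keeping long cohorts cheap).
#' @param prosody,syllable,phoneme two-element `c(rate_hz, depth)` vectors;
#'   rates must lie in the nominal bands (1-4, 4-12, 12-40 Hz) and depths
#'   in `[0, 1)`.
#' @param coupling_kappa slow->fast phase-gating strength in `[0, 1]`.
#' @param jitter_sd cycle-to-cycle rate jitter as a fraction of the nominal
#'   rate (default 0.1), realized as a smoothed frequency random walk.
#' @param carrier `"white_noise"` or `"bandpass_noise_above_40hz"`.
#' @param snr_db signal-to-noise ratio of additive white noise (default 20).
#' @param latent_grid_hz grid of the stored ground-truth envelopes.
#' @param seed RNG seed; the same spec and seed give a bit-identical signal.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(duration_s = 10, rate_hz = 2000,
                       prosody = c(2, 0.8), syllable = c(6, 0.6),
                       phoneme = c(20, 0.4), coupling_kappa = 0,
                       jitter_sd = 0.1,
                       carrier = c("white_noise", "bandpass_noise_above_40hz"),
                       snr_db = 20, latent_grid_hz = 160, seed = 1) {
  carrier <- match.arg(carrier)
  chk <- function(x, lo, hi, what) {
    if (x[1] < lo || x[1] > hi) stop(what, " rate must lie in [", lo, ", ", hi, "] Hz")
    if (x[2] < 0 || x[2] >= 1) stop(what, " depth must lie in [0, 1)")
  }
  chk(prosody, 1, 4, "prosody"); chk(syllable, 4, 12, "syllable")
  chk(phoneme, 12, 40, "phoneme")
  stopifnot(coupling_kappa >= 0, coupling_kappa <= 1, jitter_sd >= 0,
            duration_s > 0, rate_hz > 2 * 40)
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 prosody = prosody, syllable = syllable, phoneme = phoneme,
                 coupling_kappa = coupling_kappa, jitter_sd = jitter_sd,
                 carrier = carrier, snr_db = snr_db,
                 latent_grid_hz = latent_grid_hz, seed = as.integer(seed)),
            class = "synth_spec")
}

# Unit jittered oscillation at nominal rate f on a grid: the instantaneous
# frequency is f * (1 + jitter_sd * z) with z an AR(1) process whose
# correlation time is one nominal cycle.
jitter_osc <- function(n, grid_hz, f, jitter_sd, phase0 = 0) {
  if (jitter_sd > 0) {
    phi <- exp(-f / grid_hz)
    innov <- stats::rnorm(n) * sqrt(1 - phi^2)
    z <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  } else {
    z <- numeric(n)
  }
  finst <- pmax(f * (1 + jitter_sd * z), 0.05 * f)
  sin(phase0 + 2 * pi * cumsum(finst) / grid_hz)
}

#' Generate one synthetic nested-AM sample
#'
#' @param spec a [synth_spec()].
#' @param meta optional metadata list (`sample_id`, `role`, `group`,
#'   `dyad_id`, `speaker_id`, `topic`) for the embedded [speech_sample()].
#' @param audio generate the full-rate waveform (default TRUE); with
#'   `FALSE` only the latent-grid ground-truth envelopes are produced,
#'   which is orders of magnitude cheaper for statistics-level simulations.
#' @return object of class `synth_sample`: `sample` (a [speech_sample()],
#'   or NULL when `audio = FALSE`), `truth` (named list of latent-grid
#'   envelopes `low_delta`, `delta`, `theta_alpha`, `beta_gamma`),
#'   `truth_grid_hz`, `carrier`, `spec`.
#' @export
synth_generate <- function(spec, meta = list(), audio = TRUE) {
  set.seed(spec$seed)
  fl <- spec$latent_grid_hz
  nl <- round(spec$duration_s * fl)
  kap <- spec$coupling_kappa

  s_p <- jitter_osc(nl, fl, spec$prosody[1], spec$jitter_sd,
                    phase0 = stats::runif(1, 0, 2 * pi))
  s_s <- jitter_osc(nl, fl, spec$syllable[1], spec$jitter_sd,
                    phase0 = stats::runif(1, 0, 2 * pi))
  s_f <- jitter_osc(nl, fl, spec$phoneme[1], spec$jitter_sd,
                    phase0 = stats::runif(1, 0, 2 * pi))

  gate <- function(s_slow) (1 + (kap / 2) * s_slow) / sqrt(1 + kap^2 / 8)
  e_p <- 1 + spec$prosody[2] * s_p
  e_s <- 1 + spec$syllable[2] * gate(s_p) * s_s
  e_f <- 1 + spec$phoneme[2] * gate(s_s) * s_f
  truth <- list(low_delta = rep(1, nl), delta = e_p,
                theta_alpha = e_s, beta_gamma = e_f)

  sample <- NULL
  carrier <- NULL
  if (audio) {
    T <- round(spec$duration_s * spec$rate_hz)
    d <- spec$rate_hz / fl
    carrier <- stats::rnorm(T)
    if (spec$carrier == "bandpass_noise_above_40hz") {
      lo <- lowpass_fft(carrier, spec$rate_hz, 45)
      carrier <- carrier - lo
      carrier <- carrier / sd_pop(carrier)
    }
    m <- upsample_linear(e_p, d, T) * upsample_linear(e_s, d, T) *
      upsample_linear(e_f, d, T)
    clean <- m * carrier
    noise_sd <- sd_pop(clean) * 10^(-spec$snr_db / 20)
    wav <- clean + stats::rnorm(T) * noise_sd
    meta <- utils::modifyList(list(sample_id = paste0("synth", spec$seed),
                                   role = "respondent", group = "NT",
                                   dyad_id = "d1"), meta)
    sample <- speech_sample(meta$sample_id, wav, spec$rate_hz, meta$role,
                            meta$group, dyad_id = meta$dyad_id,
                            speaker_id = meta$speaker_id,
                            topic = meta$topic %||% NA_character_)
  }
  structure(list(sample = sample, truth = truth, truth_grid_hz = fl,
                 carrier = carrier, spec = spec),
            class = "synth_sample")
}

#' Rebuild the pre-noise waveform from ground-truth envelopes
#'
#' Upsamples each truth envelope linearly to the signal grid and multiplies
#' by the carrier — exactly the construction used inside [synth_generate()],
#' so the result equals the pre-noise waveform bitwise.
#'
#' @param synth a [synth_generate()] result produced with `audio = TRUE`.
#' @return numeric vector at the signal rate.
#' @export
synth_reconstruct <- function(synth) {
  if (is.null(synth$carrier)) stop("sample was generated with audio = FALSE")
  T <- length(synth$carrier)
  d <- synth$spec$rate_hz / synth$truth_grid_hz
  upsample_linear(synth$truth$delta, d, T) *
    upsample_linear(synth$truth$theta_alpha, d, T) *
    upsample_linear(synth$truth$beta_gamma, d, T) *
    synth$carrier
}

#' Envelope-recovery correlation against ground truth
#'
#' Pearson correlation between a recovered hierarchy envelope and the
#' generator's ground-truth envelope, after interpolating both onto the
#' coarser of the two time grids.
#'
#' @param hierarchy an [pad_cascade()] result.
#' @param synth the [synth_generate()] result the sample came from.
#' @param band band name (`"delta"`, `"theta_alpha"`, `"beta_gamma"`).
#' @return correlation coefficient.
#' @export
envelope_recovery <- function(hierarchy, synth, band) {
  est <- hierarchy$bands[[band]]
  tru <- synth$truth[[band]]
  t_est <- (seq_along(est) - 1) / hierarchy$grid_hz
  t_tru <- (seq_along(tru) - 1) / synth$truth_grid_hz
  if (hierarchy$grid_hz >= synth$truth_grid_hz) {
    est <- stats::approx(t_est, est, t_tru, rule = 2)$y
  } else {
    tru <- stats::approx(t_tru, tru, t_est, rule = 2)$y
  }
  stats::cor(est, tru)
}

# Beta shape parameters from a mean and standard deviation.
beta_ab <- function(mean, sd) {
  v <- sd^2
  k <- mean * (1 - mean) / v - 1
  c(a = mean * k, b = (1 - mean) * k)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Group presets for cohort generation
#'
#' NT-like speech carries strong prosody (depth centred on 0.7) and strong
#' slow->fast coupling (kappa 0.7); AUT-like speech weak prosody (0.2) and
#' weak coupling (0.2). Syllable and phoneme depths are drawn from the same
#' distribution in both groups.
#'
#' @return nested list of preset parameters, overridable via
#'   `preset_overrides` in [generate_cohort()].
#' @export
cohort_presets <- function() {
  list(
    NT = list(prosody_depth_mean = 0.7, prosody_depth_sd = 0.10, kappa = 0.7),
    AUT = list(prosody_depth_mean = 0.2, prosody_depth_sd = 0.08, kappa = 0.2),
    syllable_depth_mean = 0.6, syllable_depth_sd = 0.08,
    phoneme_depth_mean = 0.4, phoneme_depth_sd = 0.08,
    kappa_sd = 0.05,
    prosody_rate = 2, syllable_rate = 6, phoneme_rate = 20,
    rate_jitter_frac = 0.15,     # per-sample jitter of the nominal rates
    duration_range = c(10, 30),
    dyad_alpha = 0.05, dyad_beta = 0.9, dyad_noise_sd = 0.08,
    sample_depth_sd = 0.05,      # per-sample jitter around the dyad depth
    n_dyads = c(AUT = 8, NT = 6),
    rate_hz = 2000, snr_db = 20, jitter_sd = 0.1, latent_grid_hz = 160
  )
}

#' Generate a synthetic conversational cohort
#'
#' Builds four groups (`AUT_speech`, `NT_speech`, `AUT_directed`,
#' `NT_directed`) of `n_per_group` samples each, spread round-robin over
#' the dyads of each respondent group. Each dyad has one respondent whose
#' prosody depth is drawn from the group preset and one questioner whose
#' per-dyad prosody depth follows `alpha + beta * respondent_depth + noise`
#' (`beta > 0` induces the dyadic questioner-respondent correlation).
#' Questioner samples inherit the respondent group's coupling preset, so
#' AUT-directed speech is both weak-prosody and weakly coupled, mirroring
#' the respondent contrast.
#'
#' @param n_per_group samples per group (>= 2).
#' @param preset_overrides named list merged over [cohort_presets()].
#' @param seed cohort seed; all per-sample seeds derive from it.
#' @param audio generate waveforms (default TRUE); `FALSE` produces
#'   ground-truth envelopes only.
#' @return list with `manifest` (data frame: sample_id, role, group,
#'   direction_label, dyad_id, speaker_id, topic, duration_s, and the
#'   generating depths/kappa), `samples` (list of [synth_generate()]
#'   results, same order), `presets`.
#' @export
generate_cohort <- function(n_per_group = 30, preset_overrides = list(),
                            seed = 1, audio = TRUE) {
  stopifnot(n_per_group >= 2)
  pr <- utils::modifyList(cohort_presets(), preset_overrides)
  set.seed(seed)

  topics <- c("sweetness", "insults", "loneliness", "gloom", "clients",
              "hate", "transportation", "kindness", "agile", "ginger",
              "attractiveness", "thoughtfulness")

  dyads <- list()
  for (g in c("AUT", "NT")) {
    nd <- pr$n_dyads[[g]]
    ab <- beta_ab(pr[[g]]$prosody_depth_mean, pr[[g]]$prosody_depth_sd)
    for (i in seq_len(nd)) {
      dp_r <- clamp(stats::rbeta(1, ab["a"], ab["b"]), 0.02, 0.95)
      dp_q <- clamp(pr$dyad_alpha + pr$dyad_beta * dp_r +
                      stats::rnorm(1, 0, pr$dyad_noise_sd), 0.02, 0.95)
      id <- sprintf("%s%02d", tolower(g), i)
      dyads[[id]] <- list(dyad_id = id, group = g, depth_r = dp_r, depth_q = dp_q,
                          questioner_id = paste0("Q", 1 + (length(dyads) %% 2)))
    }
  }

  groups <- c("AUT_speech", "NT_speech", "AUT_directed", "NT_directed")
  manifest <- list()
  samples <- list()
  k <- 0L
  ab_s <- beta_ab(pr$syllable_depth_mean, pr$syllable_depth_sd)
  ab_f <- beta_ab(pr$phoneme_depth_mean, pr$phoneme_depth_sd)
  for (gl in groups) {
    grp <- sub("_.*", "", gl)
    role <- if (grepl("_speech$", gl)) "respondent" else "questioner"
    gd <- Filter(function(d) d$group == grp, dyads)
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      dy <- gd[[1 + (i - 1) %% length(gd)]]
      base_depth <- if (role == "respondent") dy$depth_r else dy$depth_q
      dp <- clamp(base_depth + stats::rnorm(1, 0, pr$sample_depth_sd), 0.02, 0.95)
      ds <- clamp(stats::rbeta(1, ab_s["a"], ab_s["b"]), 0.02, 0.95)
      df_ <- clamp(stats::rbeta(1, ab_f["a"], ab_f["b"]), 0.02, 0.95)
      kap <- clamp(stats::rnorm(1, pr[[grp]]$kappa, pr$kappa_sd), 0, 0.95)
      dur <- stats::runif(1, pr$duration_range[1], pr$duration_range[2])
      jrate <- function(f, lo, hi) {
        clamp(f * (1 + stats::rnorm(1, 0, pr$rate_jitter_frac)), lo, hi)
      }
      sp <- synth_spec(
        duration_s = dur, rate_hz = pr$rate_hz,
        prosody = c(jrate(pr$prosody_rate, 1.2, 3.8), dp),
        syllable = c(jrate(pr$syllable_rate, 4.2, 11.5), ds),
        phoneme = c(jrate(pr$phoneme_rate, 12.5, 38), df_),
        coupling_kappa = kap, jitter_sd = pr$jitter_sd,
        snr_db = pr$snr_db, latent_grid_hz = pr$latent_grid_hz,
        seed = derive_seed(seed, k))
      sid <- sprintf("s%04d", k)
      speaker <- if (role == "respondent") paste0(dy$dyad_id, "_R") else dy$questioner_id
      meta <- list(sample_id = sid, role = role, group = grp,
                   dyad_id = dy$dyad_id, speaker_id = speaker,
                   topic = topics[1 + (i - 1) %% length(topics)])
      samples[[k]] <- synth_generate(sp, meta, audio = audio)
      manifest[[k]] <- data.frame(
        sample_id = sid, role = role, group = grp, direction_label = gl,
        dyad_id = dy$dyad_id, speaker_id = speaker, topic = meta$topic,
        duration_s = dur, prosody_depth = dp, syllable_depth = ds,
        phoneme_depth = df_, kappa = kap, seed = sp$seed,
        stringsAsFactors = FALSE)
    }
  }
  list(manifest = do.call(rbind, manifest), samples = samples, presets = pr)
}

#' Write a cohort to WAV files plus a manifest CSV
#'
#' Emits the exact dialect [read_manifest()] expects, with one float WAV
#' per sample, and the ground-truth envelopes in the [write_am_hierarchy()]
#' CSV dialect alongside.
#'
#' @param cohort a [generate_cohort()] result with `audio = TRUE`.
#' @param dir output directory (created if needed).
#' @param truth also write ground-truth envelope CSVs (default FALSE).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$file <- file.path(dir, paste0(man$sample_id, ".wav"))
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    if (is.null(s$sample)) stop("cohort was generated with audio = FALSE")
    write_sample(s$sample, man$file[i])
    if (truth) {
      h <- list(bands = s$truth, band_edges = band_edges(),
                grid_hz = s$truth_grid_hz,
                source_sample_id = man$sample_id[i],
                reconstruction_error = 0)
      class(h) <- "am_hierarchy"
      write_am_hierarchy(h, file.path(dir, paste0(man$sample_id, "_truth.csv")))
    }
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man[, c("file", "sample_id", "role", "group", "dyad_id",
                           "speaker_id", "topic")], path, row.names = FALSE)
  invisible(path)
}
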