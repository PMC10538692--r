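# End-to-end orchestration: audio (or demo cohort) -> normalization ->
# PAD cascade -> band powers and spectra -> transfer entropy -> group
# statistics -> report. Deterministic: a fixed config and seed reproduce
# every CSV byte-identically (single-threaded, sample order fixed by
# sample_id sort). Per-sample results are cached in the run directory so a
# partially completed run can be resumed without recomputation.

#' Pipeline run configuration
#'
#' @param manifest path to a manifest CSV ([read_manifest()] dialect), or
#'   NULL for demo mode (a synthetic cohort is generated).
#' @param out_dir output run directory.
#' @param latent_grid_hz latent envelope grid for the cascade (default 160).
#' @param cascade_cutoffs_hz fast-to-slow demodulation cutoffs; the
#'   default 40/12/4/1 yields the low-delta, delta, theta-alpha and
#'   beta-gamma hierarchy.
#' @param te_rate_hz,te_history_L,te_n_bins,te_n_surrogates transfer
#'   entropy settings.
#' @param alpha significance threshold.
#' @param n_permutations permutations for the group contrasts.
#' @param min_duration_s sample inclusion threshold (default 10 s).
#' @param trim_silence apply the edge-silence trimmer (default FALSE).
#' @param seed master seed for every stochastic step.
#' @param demo_n_per_group,demo_overrides demo-mode cohort settings.
#' @return object of class `run_config`.
#' @export
run_config <- function(manifest = NULL, out_dir = tempfile("speechrhythm_run"),
                       latent_grid_hz = 160,
                       cascade_cutoffs_hz = c(40, 12, 4, 1),
                       te_rate_hz = 120, te_history_L = 1, te_n_bins = 4,
                       te_n_surrogates = 19,
                       alpha = 0.05, n_permutations = 999,
                       min_duration_s = 10, trim_silence = FALSE,
                       seed = 1, demo_n_per_group = 5,
                       demo_overrides = list()) {
  structure(list(manifest = manifest, out_dir = out_dir,
                 latent_grid_hz = latent_grid_hz,
                 cascade_cutoffs_hz = cascade_cutoffs_hz,
                 te_rate_hz = te_rate_hz, te_history_L = te_history_L,
                 te_n_bins = te_n_bins, te_n_surrogates = te_n_surrogates,
                 alpha = alpha, n_permutations = n_permutations,
                 min_duration_s = min_duration_s,
                 trim_silence = trim_silence,
                 seed = seed, demo_n_per_group = demo_n_per_group,
                 demo_overrides = demo_overrides),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Schema, band-edge and Nyquist checks. Returns diagnostics instead of
#' throwing.
#'
#' @param config a [run_config()].
#' @return character vector of diagnostics (empty when clean).
#' @export
validate_config <- function(config) {
  d <- character(0)
  cuts <- config$cascade_cutoffs_hz
  if (!identical(as.numeric(cuts), c(40, 4, 1)) &&
      !identical(as.numeric(cuts), c(40, 12, 4, 1))) {
    if (is.unsorted(rev(cuts))) d <- c(d, "cascade cutoffs must be ordered fast to slow")
    if (!identical(as.numeric(sort(cuts, decreasing = TRUE)), c(40, 12, 4, 1))) {
      d <- c(d, "non-standard band edges (expected 40/12/4/1 Hz cutoffs)")
    }
  }
  if (config$latent_grid_hz < 4 * max(cuts)) {
    d <- c(d, sprintf("latent grid %g Hz below 4x the fastest cutoff (%g Hz)",
                      config$latent_grid_hz, max(cuts)))
  }
  if (config$te_rate_hz < 2 * 40) {
    d <- c(d, sprintf("te_rate_hz = %g gives no Nyquist margin for the 12-40 Hz band",
                      config$te_rate_hz))
  }
  if (config$alpha <= 0 || config$alpha >= 1) d <- c(d, "alpha outside (0, 1)")
  if (config$n_permutations < 1) d <- c(d, "n_permutations must be >= 1")
  if (is.null(config$manifest) && config$demo_n_per_group < 2) {
    d <- c(d, "demo mode needs n_per_group >= 2")
  }
  d
}

process_sample <- function(sample, config) {
  sample <- zscore_normalize(sample)
  if (isTRUE(config$trim_silence)) sample <- trim_silence(sample)
  configs <- lapply(config$cascade_cutoffs_hz, pad_config,
                    latent_grid_hz = config$latent_grid_hz)
  h <- pad_cascade(sample, configs)
  bp <- hierarchy_band_powers(h, min_duration_s = min(config$min_duration_s,
                                                      sample$duration_s))
  te <- band_pair_te(h, te_rate_hz = config$te_rate_hz,
                     history_L = config$te_history_L,
                     n_bins = config$te_n_bins,
                     n_surrogates = config$te_n_surrogates,
                     seed = derive_seed(config$seed, utf8_sum(sample$sample_id)))
  te_wide <- stats::setNames(te$te_bits, paste0("te_", te$pair, "_", te$direction))
  feat <- cbind(bp,
                data.frame(speaker_id = sample$speaker_id,
                           direction_label = sample$direction_label,
                           dyad_id = sample$dyad_id,
                           role = sample$role,
                           duration_s = sample$duration_s,
                           reconstruction_error = h$reconstruction_error,
                           converged = h$round1$converged,
                           stringsAsFactors = FALSE),
                as.data.frame(as.list(te_wide)))
  list(features = feat, te = te, hierarchy = h)
}

utf8_sum <- function(s) sum(utf8ToInt(s))

#' Run the full analysis pipeline
#'
#' Executes every stage over a manifest of WAV files, or over a freshly
#' generated demo cohort when `config$manifest` is NULL. Writes
#' `features.csv` (one row per sample), `te.csv` (tidy transfer entropy),
#' `group_spectra.csv`, `stats.json`, `config.yaml`, `hashes.csv`
#' (content hashes of every table) and a scalogram PNG per direction label
#' into the run directory. Per-sample failures are logged and skipped; the
#' run aborts only if more than half the samples fail.
#'
#' @param config a [run_config()].
#' @param save_figures write scalogram PNGs (default TRUE).
#' @return list with `features`, `te`, `stats`, `group_spectra`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), save_figures = TRUE) {
  diags <- validate_config(config)
  if (length(diags)) warning("config diagnostics: ", paste(diags, collapse = "; "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)

  # ---- assemble samples ----
  if (is.null(config$manifest)) {
    cohort <- generate_cohort(config$demo_n_per_group,
                              preset_overrides = config$demo_overrides,
                              seed = config$seed, audio = TRUE)
    samples <- lapply(cohort$samples, `[[`, "sample")
  } else {
    man <- read_manifest(config$manifest)
    samples <- lapply(seq_len(nrow(man)), function(i) {
      load_sample(man$file[i], man[i, ])
    })
  }
  samples <- filter_samples(samples, config$min_duration_s)
  ord <- order(vapply(samples, `[[`, character(1), "sample_id"))
  samples <- samples[ord]

  # ---- per-sample processing (cached) ----
  feats <- list(); tes <- list(); specs <- list()
  failures <- character(0)
  for (s in samples) {
    # the cache file is the single source of truth: fresh runs write it and
    # then load it back, so resumed and fresh runs yield identical bytes
    cache <- file.path(cache_dir, paste0(s$sample_id, ".json"))
    if (!file.exists(cache)) {
      res <- tryCatch({
        pr <- process_sample(s, config)
        sp <- modulation_spectrum(
          pr$hierarchy$bands$delta * pr$hierarchy$bands$theta_alpha *
            pr$hierarchy$bands$beta_gamma,
          pr$hierarchy$grid_hz, sample_id = s$sample_id,
          band_name_of_source = "product",
          min_duration_s = min(config$min_duration_s, s$duration_s))
        list(pr = pr, sp = sp)
      }, error = function(e) {
        message("sample ", s$sample_id, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) { failures <- c(failures, s$sample_id); next }
      jsonlite::write_json(
        list(features = res$pr$features, te = res$pr$te,
             spectrum = list(freqs_hz = res$sp$freqs_hz, power = res$sp$power,
                             band_power = as.list(res$sp$band_power),
                             grid_hz = res$sp$grid_hz)),
        cache, auto_unbox = TRUE, digits = NA)
    }
    cc <- jsonlite::read_json(cache, simplifyVector = TRUE)
    feats[[s$sample_id]] <- as.data.frame(cc$features, stringsAsFactors = FALSE)
    tes[[s$sample_id]] <- as.data.frame(cc$te, stringsAsFactors = FALSE)
    specs[[s$sample_id]] <- structure(
      list(freqs_hz = cc$spectrum$freqs_hz, power = cc$spectrum$power,
           band_power = unlist(cc$spectrum$band_power),
           sample_id = s$sample_id, band_name_of_source = "product",
           grid_hz = cc$spectrum$grid_hz),
      class = "modulation_spectrum")
  }
  if (length(failures) > length(samples) / 2) {
    stop("more than half the samples failed: ", paste(failures, collapse = ", "))
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  te_table <- do.call(rbind, tes)
  rownames(te_table) <- NULL

  grouping <- stats::setNames(features$direction_label, features$sample_id)
  gspec <- group_average_spectra(specs, grouping)

  # ---- statistics ----
  stats_report <- pipeline_stats(features, config)

  # ---- outputs ----
  f_feat <- file.path(config$out_dir, "features.csv")
  f_te <- file.path(config$out_dir, "te.csv")
  f_gs <- file.path(config$out_dir, "group_spectra.csv")
  utils::write.csv(features, f_feat, row.names = FALSE)
  utils::write.csv(te_table, f_te, row.names = FALSE)
  gs_tidy <- do.call(rbind, lapply(names(gspec), function(g) {
    data.frame(direction_label = g, freq_hz = gspec[[g]]$freqs_hz,
               power = gspec[[g]]$power, n_samples = gspec[[g]]$n_samples,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(gs_tidy, f_gs, row.names = FALSE)
  jsonlite::write_json(stats_report, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(stats_tidy(stats_report),
                   file.path(config$out_dir, "stats.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))

  if (save_figures) {
    for (g in names(gspec)) {
      id <- names(which(grouping == g))[1]
      sp <- specs[[id]]
      grDevices::png(file.path(config$out_dir, paste0("spectrum_", g, ".png")),
                     width = 600, height = 400)
      sel <- sp$freqs_hz > 0
      graphics::plot(sp$freqs_hz[sel], sp$power[sel], type = "l", log = "x",
                     xlim = c(0.5, 40), xlab = "modulation rate (Hz)",
                     ylab = "power", main = g)
      grDevices::dev.off()
      # scalogram of one sample's product envelope per group
      s_obj <- samples[[which(vapply(samples, `[[`, character(1),
                                     "sample_id") == id)]]
      env_h <- tryCatch(pad_cascade(zscore_normalize(s_obj),
                                    lapply(config$cascade_cutoffs_hz, pad_config,
                                           latent_grid_hz = config$latent_grid_hz)),
                        error = function(e) NULL)
      if (!is.null(env_h)) {
        prod_env <- env_h$bands$low_delta * env_h$bands$delta *
          env_h$bands$theta_alpha * env_h$bands$beta_gamma
        sc <- scalogram(prod_env, env_h$grid_hz, seed = config$seed)
        write_scalogram(sc, file.path(config$out_dir,
                                      paste0("scalogram_", g, ".png")),
                        main = g)
      }
    }
  }

  files <- c(f_feat, f_te, f_gs)
  hashes <- data.frame(file = basename(files),
                       md5 = vapply(files, function(f) unname(tools::md5sum(f)),
                                    character(1)),
                       stringsAsFactors = FALSE)
  utils::write.csv(hashes, file.path(config$out_dir, "hashes.csv"),
                   row.names = FALSE)

  list(features = features, te = te_table, stats = stats_report,
       group_spectra = gspec, out_dir = config$out_dir,
       failures = failures)
}

# Flatten the nested stats report into a tidy one-row-per-test table.
stats_tidy <- function(report) {
  rows <- list()
  add <- function(test_name, statistic, p, adj = NA_real_, effect = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      test_name = test_name, statistic = statistic, p_value = p,
      adjusted_p = adj, effect_size = effect, stringsAsFactors = FALSE)
  }
  for (an in intersect(c("respondents", "questioners"), names(report))) {
    r <- report[[an]]
    add(paste0(an, "_rhythm_interaction"), r$rhythm_interaction$statistic,
        r$rhythm_interaction$p_value, effect = r$rhythm_interaction$effect_size)
    for (i in seq_len(nrow(r$rhythm_levels))) {
      add(paste0(an, "_rhythm_", r$rhythm_levels$level[i]),
          r$rhythm_levels$mean_diff[i], r$rhythm_levels$p_value[i],
          r$rhythm_levels$adjusted_p[i])
    }
    add(paste0(an, "_te_interaction"), r$te_interaction$statistic,
        r$te_interaction$p_value, effect = r$te_interaction$effect_size)
    for (i in seq_len(nrow(r$te_levels))) {
      add(paste0(an, "_te_", r$te_levels$level[i]),
          r$te_levels$mean_diff[i], r$te_levels$p_value[i],
          r$te_levels$adjusted_p[i])
    }
  }
  if ("dyad_prosody" %in% names(report)) {
    add("dyad_prosody_correlation", report$dyad_prosody$statistic,
        report$dyad_prosody$p_value, effect = report$dyad_prosody$effect_size)
  }
  do.call(rbind, rows)
}

# Group contrasts and dyad correlation over a feature table.
pipeline_stats <- function(features, config) {
  out <- list()
  contrasts <- list(
    respondents = c("AUT_speech", "NT_speech"),
    questioners = c("AUT_directed", "NT_directed")
  )
  for (nm in names(contrasts)) {
    lv <- contrasts[[nm]]
    sub <- features[features$direction_label %in% lv, ]
    if (length(unique(sub$direction_label)) < 2) next
    long <- do.call(rbind, lapply(c("prosody", "syllable", "phoneme"), function(rh) {
      data.frame(unit = sub$sample_id, group = sub$direction_label,
                 level = rh, value = log10(sub[[paste0(rh, "_power")]] + 1e-12),
                 stringsAsFactors = FALSE)
    }))
    gc_ <- group_contrast(long, n_permutations = config$n_permutations,
                          seed = derive_seed(config$seed, utf8_sum(nm)))
    te_cols <- grep("^te_.*(top_down|bottom_up)$", names(sub), value = TRUE)
    te_long <- do.call(rbind, lapply(te_cols, function(cn) {
      data.frame(unit = sub$sample_id, group = sub$direction_label,
                 level = sub("^te_", "", cn), value = sub[[cn]],
                 stringsAsFactors = FALSE)
    }))
    te_gc <- group_contrast(te_long, n_permutations = config$n_permutations,
                            seed = derive_seed(config$seed, utf8_sum(nm) + 1))
    out[[nm]] <- list(
      rhythm_interaction = unclass(gc_$interaction),
      rhythm_levels = gc_$levels,
      rhythm_parametric = unclass(gc_$parametric),
      te_interaction = unclass(te_gc$interaction),
      te_levels = te_gc$levels
    )
  }

  # dyadic correlation of prosody power: per-dyad questioner vs respondent
  dy <- dyad_feature_pairs(features, "prosody_power")
  if (nrow(dy) >= 4) {
    dc <- dyad_correlation(dy$questioner, dy$respondent, method = "auto")
    out$dyad_prosody <- unclass(dc)
    out$dyad_prosody$n_dyads <- nrow(dy)
  }
  out$alpha <- config$alpha
  out
}

#' Per-dyad questioner/respondent feature pairs
#'
#' Averages a feature per speaker within each dyad and pairs the dyad's
#' questioner value with its respondent value.
#'
#' @param features a pipeline feature table (per sample).
#' @param feature feature column name (default `"prosody_power"`).
#' @return data frame with `dyad_id`, `questioner`, `respondent`.
#' @export
dyad_feature_pairs <- function(features, feature = "prosody_power") {
  rows <- list()
  for (d in unique(features$dyad_id)) {
    sub <- features[features$dyad_id == d, ]
    qv <- sub[[feature]][sub$role == "questioner"]
    rv <- sub[[feature]][sub$role == "respondent"]
    if (length(qv) && length(rv)) {
      rows[[d]] <- data.frame(dyad_id = d, questioner = mean(qv),
                              respondent = mean(rv), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(dyad_id = character(0),
                                       questioner = numeric(0),
                                       respondent = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
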