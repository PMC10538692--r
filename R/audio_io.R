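# Sample loading, inclusion rules and normalization.
#
# A speech corpus is described by a manifest (CSV) whose rows point at WAV
# files and carry the conversational metadata: who is speaking (questioner
# or respondent), the diagnostic group of the dyad's respondent (AUT or NT),
# and the dyad identity. The derived direction label classifies each sample
# into the four analysis groups: AUT_speech / NT_speech (respondents) and
# AUT_directed / NT_directed (the questioner addressing that respondent).

band_edges <- function() {
  data.frame(
    band = c("low_delta", "delta", "theta_alpha", "beta_gamma"),
    lo_hz = c(0, 1, 4, 12),
    hi_hz = c(1, 4, 12, 40),
    stringsAsFactors = FALSE
  )
}

rhythm_of_band <- function(band) {
  c(delta = "prosody", theta_alpha = "syllable", beta_gamma = "phoneme",
    low_delta = "low_delta")[band]
}

#' Direction label of a speech sample
#'
#' The label is a pure function of the speaker's role and the diagnostic
#' group of the dyad's respondent: respondents produce `AUT_speech` /
#' `NT_speech`; the (neurotypical) questioner produces `AUT_directed` /
#' `NT_directed` speech according to whom they address.
#'
#' @param role `"questioner"` or `"respondent"`.
#' @param group respondent group of the dyad, `"AUT"` or `"NT"`.
#' @return one of `"AUT_speech"`, `"NT_speech"`, `"AUT_directed"`,
#'   `"NT_directed"`.
#' @export
direction_label <- function(role, group) {
  role <- match.arg(role, c("questioner", "respondent"))
  group <- match.arg(group, c("AUT", "NT"))
  if (role == "respondent") paste0(group, "_speech") else paste0(group, "_directed")
}

#' Construct a speech sample
#'
#' @param sample_id unique sample identifier.
#' @param waveform numeric vector.
#' @param rate_hz sampling rate in Hz.
#' @param role,group speaker role and dyad respondent group (see
#'   [direction_label()]).
#' @param dyad_id dyad (conversation pair) identifier.
#' @param speaker_id speaker identifier; defaults to `dyad_id` plus role.
#' @param topic optional interview topic.
#' @param normalized logical; has the waveform been z-scored?
#' @return object of class `speech_sample`.
#' @export
speech_sample <- function(sample_id, waveform, rate_hz, role, group,
                          dyad_id = "d1", speaker_id = NULL, topic = NA_character_,
                          normalized = FALSE) {
  stopifnot(is.numeric(waveform), rate_hz > 0)
  if (length(waveform) == 0) stop("zero-length audio for sample ", sample_id)
  if (any(!is.finite(waveform))) stop("non-finite values in waveform of ", sample_id)
  role <- match.arg(role, c("questioner", "respondent"))
  group <- match.arg(group, c("AUT", "NT"))
  structure(list(
    sample_id = as.character(sample_id),
    waveform = as.numeric(waveform),
    rate_hz = rate_hz,
    role = role,
    group = group,
    direction_label = direction_label(role, group),
    dyad_id = as.character(dyad_id),
    speaker_id = speaker_id %||% paste0(dyad_id, "_", substr(role, 1, 1)),
    topic = topic,
    duration_s = length(waveform) / rate_hz,
    normalized = isTRUE(normalized)
  ), class = "speech_sample")
}

#' @export
print.speech_sample <- function(x, ...) {
  cat(sprintf("<speech_sample %s: %.2f s @ %g Hz, %s, dyad %s%s>\n",
              x$sample_id, x$duration_s, x$rate_hz, x$direction_label,
              x$dyad_id, if (x$normalized) ", z-scored" else ""))
  invisible(x)
}

#' Load one sample from a WAV file
#'
#' Stereo files are mixed down to mono by channel mean; integer PCM is
#' rescaled to real values in `[-1, 1]`. The returned waveform is raw
#' (not yet normalized).
#'
#' @param path WAV file path.
#' @param meta one manifest row (list or single-row data frame) with fields
#'   `sample_id`, `role`, `group`, `dyad_id` and optionally `speaker_id`,
#'   `topic`.
#' @return a [speech_sample()].
#' @export
load_sample <- function(path, meta) {
  w <- read_wav(path)
  if (w$rate_hz < 8000) stop("sampling rate below 8 kHz in ", path)
  wave <- if (w$n_channels > 1) colMeans(w$samples) else as.vector(w$samples)
  meta <- as.list(meta)
  speech_sample(meta$sample_id, wave, w$rate_hz, meta$role, meta$group,
                dyad_id = meta$dyad_id %||% "d1",
                speaker_id = meta$speaker_id,
                topic = meta$topic %||% NA_character_)
}

#' Read and validate a sample manifest
#'
#' Expected CSV columns: `file, sample_id, role, group, dyad_id, topic`
#' (optionally `speaker_id`). Validates that sample ids are unique and that
#' each dyad has exactly one questioner identity.
#'
#' @param path CSV path.
#' @return data frame of manifest rows.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("file", "sample_id", "role", "group", "dyad_id")
  missing <- setdiff(required, names(m))
  if (length(missing)) stop("manifest missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in manifest")
  if (!"speaker_id" %in% names(m)) {
    m$speaker_id <- paste0(m$dyad_id, "_", substr(m$role, 1, 1))
  }
  q <- m[m$role == "questioner", ]
  if (nrow(q)) {
    nq <- tapply(q$speaker_id, q$dyad_id, function(s) length(unique(s)))
    if (any(nq > 1)) stop("dyad with more than one questioner identity: ",
                          paste(names(nq)[nq > 1], collapse = ", "))
  }
  m
}

#' Z-score normalize a sample
#'
#' Centers and scales the waveform to mean 0 and standard deviation 1,
#' using the population convention (divisor T). Idempotent and invariant to
#' affine transforms of the input.
#'
#' @param sample a [speech_sample()].
#' @return the sample with normalized waveform.
#' @export
zscore_normalize <- function(sample) {
  y <- sample$waveform
  s <- sd_pop(y)
  if (s == 0) stop("zero variance: cannot z-score a constant waveform")
  sample$waveform <- (y - mean(y)) / s
  sample$normalized <- TRUE
  sample
}

#' Apply the minimum-duration inclusion rule
#'
#' Keeps exactly the samples at least `min_duration_s` long, in their
#' original order. The study design records each excerpt with lead-in and
#' lead-out silence and excludes excerpts shorter than 10 s.
#'
#' @param samples list of [speech_sample()] objects.
#' @param min_duration_s inclusion threshold in seconds (default 10).
#' @return filtered list.
#' @export
filter_samples <- function(samples, min_duration_s = 10) {
  Filter(function(s) s$duration_s >= min_duration_s, samples)
}

#' Trim leading/trailing low-energy frames (optional, off by default)
#'
#' Frames of 50 ms whose RMS is below `threshold` times the global RMS are
#' stripped from both ends. Interior frames are never removed. Recording
#' protocols that pad each excerpt with silence can be undone with this
#' before analysis; the default pipeline retains the padding.
#'
#' @param sample a [speech_sample()].
#' @param threshold fraction of global RMS below which an edge frame counts
#'   as silent (default 0.05).
#' @param frame_s frame length in seconds (default 0.05).
#' @return the trimmed sample.
#' @export
trim_silence <- function(sample, threshold = 0.05, frame_s = 0.05) {
  y <- sample$waveform
  flen <- max(1L, round(frame_s * sample$rate_hz))
  nfr <- length(y) %/% flen
  if (nfr < 3) return(sample)
  fr <- matrix(y[seq_len(nfr * flen)], nrow = flen)
  rms <- sqrt(colMeans(fr^2))
  keep <- rms >= threshold * sqrt(mean(y^2))
  first <- which(keep)[1]
  last <- utils::tail(which(keep), 1)
  if (is.na(first)) return(sample)
  i0 <- (first - 1) * flen + 1
  i1 <- min(length(y), last * flen)
  sample$waveform <- y[i0:i1]
  sample$duration_s <- length(sample$waveform) / sample$rate_hz
  sample
}

#' Write a speech sample to WAV
#'
#' Normalized samples are written as IEEE float so the round trip is exact;
#' raw samples may be written as 16-bit PCM.
#'
#' @param sample a [speech_sample()].
#' @param path output path.
#' @param format `"float32"` or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample, path, format = c("float32", "pcm16")) {
  write_wav(sample$waveform, sample$rate_hz, path, match.arg(format))
}
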