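# Minimal RIFF/WAVE reader and writer (PCM 16/24/32-bit and IEEE float).
# The study's recordings are plain 44.1 kHz/16-bit mono WAV; only the
# canonical chunk layout is supported, which covers every file the rest of
# the package writes.

#' Read a RIFF/WAVE audio file
#'
#' Supports uncompressed PCM (16/24/32-bit integer) and IEEE-float (32/64-bit)
#' WAV, mono or multi-channel. Integer PCM is rescaled to `[-1, 1]` by
#' dividing by `2^(bits-1)`.
#'
#' @param path path to a `.wav` file.
#' @return list with `rate_hz`, `bits`, `n_channels`, and `samples`
#'   (a channels x frames matrix of doubles).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format    = readBin(body[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        channels  = readBin(body[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        rate      = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(body[15:16], "integer", 1, 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("missing fmt chunk in ", path)
  if (is.null(data_raw) || length(data_raw) == 0) stop("zero-length audio in ", path)
  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) carries the real format in its first
  # sub-format bytes; treat as PCM/float by bit depth.
  is_float <- fmt$format == 3L
  if (!fmt$format %in% c(1L, 3L, 65534L)) {
    stop("unsupported WAV format code ", fmt$format, " in ", path)
  }
  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% bytes
  if (is_float) {
    vals <- readBin(data_raw, "double", n, bytes, endian = "little")
  } else if (fmt$bits == 16L) {
    vals <- readBin(data_raw, "integer", n, 2, endian = "little", signed = TRUE) / 32768
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    vals <- v / 8388608
  } else if (fmt$bits == 32L) {
    vals <- readBin(data_raw, "integer", n, 4, endian = "little") / 2147483648
  } else {
    stop("unsupported bit depth ", fmt$bits, " in ", path)
  }
  frames <- n %/% fmt$channels
  samples <- matrix(vals[seq_len(frames * fmt$channels)], nrow = fmt$channels)
  list(rate_hz = fmt$rate, bits = fmt$bits, n_channels = fmt$channels,
       samples = samples)
}

#' Write a RIFF/WAVE audio file
#'
#' @param samples numeric vector (mono) or channels x frames matrix, on the
#'   `[-1, 1]` scale for integer formats.
#' @param rate_hz sampling rate in Hz.
#' @param path output path.
#' @param format `"float32"` (IEEE float, default: lossless for normalized
#'   signals) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate_hz, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  ch <- nrow(samples)
  interleaved <- as.vector(samples)
  if (format == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    ints <- as.integer(pmax(pmin(round(interleaved * 32768), 32767), -32768))
    payload_size <- length(ints) * 2L
  } else {
    fmt_code <- 3L; bits <- 32L
    payload_size <- length(interleaved) * 4L
  }
  block_align <- ch * bits %/% 8
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(as.integer(ch), con, 2, endian = "little")
  writeBin(as.integer(rate_hz), con, 4, endian = "little")
  writeBin(as.integer(rate_hz * block_align), con, 4, endian = "little")
  writeBin(as.integer(block_align), con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_size), con, 4, endian = "little")
  if (format == "pcm16") {
    writeBin(ints, con, 2, endian = "little")
  } else {
    writeBin(interleaved, con, 4, endian = "little")
  }
  invisible(path)
}
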