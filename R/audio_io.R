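# Audio container and plain PCM WAV I/O.

#' An audio track
#'
#' @param samples amplitudes in `[-1, 1]` (mono numeric vector)
#' @param fs sampling rate, Hz
#' @return object of class `audio_track` with `samples`, `fs`, `duration`
#' @export
audio_track <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (!is_finite_num(fs) || fs <= 0) {
    abort_mgce("sampling rate must be positive", "mgce_input_error")
  }
  if (!all(is.finite(samples))) {
    abort_mgce("samples must be finite", "mgce_input_error")
  }
  structure(list(samples = samples, fs = fs,
                 duration = length(samples) / fs),
            class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("<audio_track> %.2f s at %g Hz (%d samples)\n",
              x$duration, x$fs, length(x$samples)))
  invisible(x)
}

#' Read a PCM WAV file
#'
#' Supports uncompressed RIFF/WAVE, 16- or 24-bit integer PCM, any
#' sampling rate >= 8 kHz; multichannel input is averaged to mono.
#'
#' @param path WAV file
#' @return an [audio_track()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort_mgce(sprintf("audio file not found: %s", path), "mgce_input_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort_mgce("not a RIFF file", "mgce_parse_error")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort_mgce("not a WAVE file", "mgce_parse_error")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        fs = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(fmt) || is.null(data)) {
    abort_mgce("missing fmt or data chunk", "mgce_parse_error")
  }
  if (fmt$audio_format != 1L || !fmt$bits %in% c(16L, 24L)) {
    abort_mgce("only 16/24-bit integer PCM WAV is supported", "mgce_parse_error")
  }
  x <- if (fmt$bits == 16L) {
    readBin(data, "integer", length(data) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else {
    b <- as.integer(data)
    n <- length(b) %/% 3
    v <- b[seq(1, 3 * n, 3)] + 256 * b[seq(2, 3 * n, 3)] +
      65536 * b[seq(3, 3 * n, 3)]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  }
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_track(x, fmt$fs)
}

#' Write an audio track as 16-bit PCM WAV
#'
#' @param track an [audio_track()]
#' @param path destination
#' @return `path`, invisibly
#' @export
write_wav <- function(track, path) {
  stopifnot(inherits(track, "audio_track"))
  x <- pmax(-1, pmin(1, track$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")   # PCM
  writeBin(1L, con, 2, endian = "little")   # mono
  writeBin(as.integer(track$fs), con, 4, endian = "little")
  writeBin(as.integer(track$fs * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
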