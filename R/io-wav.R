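#' Audio clip container
#'
#' A minimal container for a mono audio signal: a numeric sample vector in
#' \[-1, 1\] plus its sampling rate in Hz.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling rate in Hz (positive scalar).
#' @return An object of class `audio_clip` with elements `samples` and `rate`.
#' @export
audio_clip <- function(samples, rate) {
  stopifnot(is.numeric(samples), length(samples) > 0L, all(is.finite(samples)))
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %g Hz (%.3f s), rms %.4g\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param clip An [audio_clip()]. Samples outside \[-1, 1\] are clipped.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmax(-1, pmin(1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")         # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(clip$rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Parses the RIFF chunk structure written by [write_wav()] (and by any other
#' writer of canonical mono 16-bit PCM files).
#'
#' @param path Input file path.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; n_chan <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      n_chan <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16L) readBin(con, "raw", sz - 16L)
      if (fmt[1] != 1L || n_chan != 1L || bits != 16L)
        stop("only mono 16-bit PCM WAV is supported")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", sz %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", sz + sz %% 2L)   # skip unknown chunk (word-aligned)
    }
  }
  if (is.null(rate) || is.null(samples)) stop("malformed WAV file: ", path)
  audio_clip(samples / 32767, rate)
}
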