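#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for single-channel 16-bit PCM. Samples are
#' expected on the nominal \code{[-1, 1]} scale and are quantized to
#' \code{int16} by scaling with 32767; values outside the range are clipped.
#'
#' @param samples numeric vector of amplitudes, nominally in \code{[-1, 1]}.
#' @param path output file path.
#' @param rate sampling rate in Hz.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(samples, path, rate = 16000L) {
  stopifnot(is.numeric(samples), length(samples) > 0L, rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Counterpart of [write_wav()]. Only uncompressed single-channel 16-bit PCM
#' is supported; samples are returned on the \code{[-1, 1]} scale
#' (dividing by 32767).
#'
#' @param path WAV file path.
#' @return an `audio_signal`: list with `samples` (numeric) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      channels <- fmt[2]
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("data chunk before fmt chunk")
      if (bits != 16L || channels != 1L) stop("only 16-bit mono supported")
      samples <- readBin(con, "integer", size %/% 2L, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  audio_signal(samples / 32767, rate)
}

#' Construct an audio signal object
#'
#' @param samples numeric amplitude sequence (dimensionless, nominally
#'   in \code{[-1, 1]}).
#' @param rate sampling rate in Hz, must be positive.
#' @return list of class `audio_signal` with `samples` and `rate`.
#' @export
audio_signal <- function(samples, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (!is.numeric(samples)) stop("samples must be numeric")
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.2f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}
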