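#' Rendered audio signal
#'
#' Container for mono audio: a numeric sample vector in `[-1, 1]` plus its
#' sample rate.
#'
#' @param samples numeric vector of audio samples, all finite, within
#'   `[-1, 1]`.
#' @param sample_rate_hz positive integer sample rate (Hz).
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate_hz) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples)))
    stop("audio samples must be finite")
  if (length(samples) && max(abs(samples)) > 1 + 1e-12)
    stop("audio samples must lie within [-1, 1]")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be positive")
  structure(list(samples = samples,
                 sample_rate_hz = as.integer(round(sample_rate_hz))),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio: %d samples @ %d Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Write audio to a WAV file
#'
#' Writes mono RIFF/WAVE: 16-bit PCM (default) or 32-bit IEEE float.
#'
#' @param audio an [audio_signal()].
#' @param path output file path.
#' @param bit_depth `16` for PCM or `"float32"`.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(audio, path, bit_depth = 16) {
  stopifnot(inherits(audio, "audio_signal"))
  float <- identical(bit_depth, "float32")
  if (!float && !identical(as.integer(bit_depth), 16L))
    stop("bit_depth must be 16 or \"float32\"")
  n <- length(audio$samples)
  bytes_per <- if (float) 4L else 2L
  data_size <- n * bytes_per
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error")) stop(sprintf("cannot write to %s", path))
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(if (float) 3L else 1L)            # format tag: PCM=1, IEEE float=3
  w16(1L)                               # mono
  w32(audio$sample_rate_hz)
  w32(audio$sample_rate_hz * bytes_per) # byte rate
  w16(bytes_per)                        # block align
  w16(8L * bytes_per)                   # bits per sample
  writeChar("data", con, eos = NULL); w32(data_size)
  if (float) {
    writeBin(audio$samples, con, size = 4L, endian = "little")
  } else {
    q <- as.integer(round(pmax(-1, pmin(1, audio$samples)) * 32767))
    writeBin(q, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' @param path WAV file path (mono, 16-bit PCM or 32-bit float).
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  r16 <- function() readBin(con, "integer", size = 2L, signed = TRUE, endian = "little")
  r32 <- function() readBin(con, "integer", size = 4L, endian = "little")
  if (!identical(readChar(con, 4L), "RIFF")) stop("not a RIFF file")
  r32()
  if (!identical(readChar(con, 4L), "WAVE")) stop("not a WAVE file")
  fmt_tag <- NA_integer_; rate <- NA_integer_; bits <- NA_integer_
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found")
    size <- r32()
    if (id == "fmt ") {
      fmt_tag <- r16(); nch <- r16(); rate <- r32(); r32(); r16(); bits <- r16()
      if (nch != 1L) stop("only mono WAV supported")
      if (size > 16L) readBin(con, "raw", n = size - 16L)
    } else if (id == "data") {
      n <- size %/% (bits %/% 8L)
      samples <- if (fmt_tag == 3L) {
        readBin(con, "numeric", n = n, size = 4L, endian = "little")
      } else if (fmt_tag == 1L && bits == 16L) {
        readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                endian = "little") / 32767
      } else stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                          fmt_tag, bits))
      return(audio_signal(samples, rate))
    } else {
      readBin(con, "raw", n = size)
    }
  }
}
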