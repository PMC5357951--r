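#' Locate the dominant spectral peak in a frequency band
#'
#' Hann-windowed FFT magnitude spectrum, maximum bin restricted to
#' `band_hz`, with parabolic interpolation of the peak position and height
#' across the three bins around the maximum (sub-bin accuracy without zero
#' padding). Silence in the band is reported as a "no peak" result, not an
#' error.
#'
#' @param audio an [audio_signal()] (1 s or more for <= 1 Hz resolution).
#' @param band_hz numeric `c(low, high)` in Hz, within Nyquist.
#' @return An object of class `spectrum_peak`: list with `frequency_hz`,
#'   `magnitude` (linear, not dB) and `found` (FALSE for silence / empty
#'   band, with `frequency_hz = NA`).
#' @examples
#' tone <- audio_signal(0.5 * sin(2 * pi * 440 * (0:44099) / 44100), 44100)
#' fft_peak(tone, c(300, 500))
#' @export
fft_peak <- function(audio, band_hz) {
  stopifnot(inherits(audio, "audio_signal") || is.list(audio))
  x <- audio$samples
  fs <- audio$sample_rate_hz
  if (length(band_hz) != 2L || band_hz[1L] >= band_hz[2L])
    stop("`band_hz` must be c(low, high) with low < high")
  if (band_hz[2L] > fs / 2)
    stop("band exceeds the Nyquist frequency")
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)  # Hann
  xw <- x * w
  mag <- Mod(stats::fft(xw))[seq_len(n %/% 2 + 1L)]
  bin <- fs / n
  freq <- (seq_len(n %/% 2 + 1L) - 1) * bin
  in_band <- which(freq >= band_hz[1L] & freq <= band_hz[2L])
  no_peak <- structure(list(frequency_hz = NA_real_, magnitude = 0,
                            found = FALSE), class = "spectrum_peak")
  if (!length(in_band)) return(no_peak)
  i <- in_band[which.max(mag[in_band])]
  if (mag[i] <= n * 1e-12) return(no_peak)
  # windowed DTFT magnitude at an arbitrary frequency (scalloping-free)
  dtft_mag <- function(f) {
    ph <- -2 * pi * f / fs * seq(0, n - 1)
    Mod(sum(xw * complex(real = cos(ph), imaginary = sin(ph))))
  }
  parab <- function(a, b, c) {
    denom <- a - 2 * b + c
    d <- if (denom != 0) 0.5 * (a - c) / denom else 0
    max(-0.5, min(0.5, d))
  }
  # stage 1: parabolic interpolation over the neighbouring FFT bins
  f <- if (i > 1L && i < length(mag))
    freq[i] + parab(mag[i - 1L], mag[i], mag[i + 1L]) * bin
  else freq[i]
  # stage 2: refine on the continuous spectrum around the first estimate
  d <- bin / 4
  m3 <- c(dtft_mag(f - d), dtft_mag(f), dtft_mag(f + d))
  f <- f + parab(m3[1L], m3[2L], m3[3L]) * d
  structure(list(frequency_hz = f, magnitude = dtft_mag(f), found = TRUE),
            class = "spectrum_peak")
}

#' @export
print.spectrum_peak <- function(x, ...) {
  if (x$found)
    cat(sprintf("spectral peak: %.3f Hz (magnitude %.4g)\n",
                x$frequency_hz, x$magnitude))
  else cat("no peak\n")
  invisible(x)
}

#' Harmonic-to-fundamental amplitude ratio
#'
#' Measures the spectral magnitude at `k * f0` relative to the magnitude
#' at `f0`, each located by [fft_peak()] within a +/-3% band. Linear
#' amplitude fractions, not dB; invariant to the overall audio amplitude.
#'
#' @param audio an [audio_signal()].
#' @param f0_hz fundamental frequency (Hz).
#' @param k integer harmonic number (`k * f0` below Nyquist).
#' @return The amplitude ratio (0 if the harmonic is absent).
#' @export
harmonic_ratio <- function(audio, f0_hz, k) {
  if (k * f0_hz > audio$sample_rate_hz / 2)
    stop("harmonic lies above the Nyquist frequency")
  fund <- fft_peak(audio, f0_hz * c(0.97, 1.03))
  if (!fund$found)
    stop("undefined ratio: no energy at the fundamental")
  harm <- fft_peak(audio, k * f0_hz * c(0.97, 1.03))
  harm$magnitude / fund$magnitude
}

#' Track the pitch of a rendered channel over time
#'
#' Splits the audio into consecutive frames of `frame_s` seconds and
#' locates the per-frame spectral peak in a +/-6% band around the
#' fundamental — wide enough to follow the half-semitone pitch modulation.
#'
#' @param audio an [audio_signal()].
#' @param f0_hz nominal fundamental (Hz).
#' @param frame_s frame length in seconds (default 1; must be at least
#'   `4 / f0_hz`).
#' @return Numeric vector of length `floor(duration / frame_s)`: tracked
#'   frequency per frame, `NA` where a frame is silent.
#' @export
pitch_track <- function(audio, f0_hz, frame_s = 1) {
  if (frame_s < 4 / f0_hz)
    stop("`frame_s` must cover at least 4 fundamental periods")
  nf <- floor(length(audio$samples) / audio$sample_rate_hz / frame_s)
  npf <- round(frame_s * audio$sample_rate_hz)
  band <- f0_hz * c(0.94, 1.06)
  vapply(seq_len(nf), function(i) {
    frame <- audio$samples[((i - 1L) * npf + 1L):(i * npf)]
    p <- fft_peak(structure(list(samples = frame,
                                 sample_rate_hz = audio$sample_rate_hz),
                            class = "audio_signal"), band)
    if (p$found) p$frequency_hz else NA_real_
  }, 0)
}
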