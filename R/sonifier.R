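#' Sonification configuration
#'
#' All parameters of the polyphonic parameter-mapping sonification. The
#' defaults reproduce the published design: one note of the D minor scale
#' per channel over two octaves, harmonics 3, 4, 5 at 15%, 5% and 5% of the
#' fundamental's amplitude (the 2nd harmonic is omitted on purpose — it
#' would collide with channels 4-6, which are octave-shifted fundamentals
#' of channels 1-3), voltage mapped to amplitude and to a pitch deviation
#' of half a semitone at full scale (a 3% frequency variation), and a
#' linear loudness-compensation ramp from 100% (lowest note) down to 30%
#' (highest note).
#'
#' @param fundamentals_hz ascending oscillator fundamentals, one per
#'   channel (Hz). Default: D minor scale 146.83, 174.61, 220.00, 293.67,
#'   349.23, 440.00.
#' @param harmonic_multipliers integer harmonic numbers added to each
#'   channel. Default `c(3, 4, 5)`.
#' @param harmonic_rel_amplitudes amplitudes of those harmonics as
#'   fractions of the fundamental's amplitude. Default `c(0.15, 0.05, 0.05)`.
#' @param pitch_mod_semitones peak pitch deviation, in semitones, at
#'   full-scale voltage. Default 0.5 (half a semitone, about +/-3%).
#' @param loudness_weights per-channel gains; default the linear ramp from
#'   1.00 to 0.30 across the ordered notes.
#' @param audio_sample_rate_hz audio rate in Hz (default 44100).
#' @param fade_s raised-cosine fade applied at both ends of the mix, in
#'   seconds (default 0.005).
#' @param output_peak peak amplitude of the normalized mix (default 0.9).
#' @return An object of class `sonification_config`.
#' @export
sonification_config <- function(
    fundamentals_hz = c(146.83, 174.61, 220.00, 293.67, 349.23, 440.00),
    harmonic_multipliers = c(3L, 4L, 5L),
    harmonic_rel_amplitudes = c(0.15, 0.05, 0.05),
    pitch_mod_semitones = 0.5,
    loudness_weights = NULL,
    audio_sample_rate_hz = 44100L,
    fade_s = 0.005,
    output_peak = 0.9) {
  n <- length(fundamentals_hz)
  if (n < 1L || any(fundamentals_hz <= 0))
    stop("`fundamentals_hz` must be positive")
  if (is.unsorted(fundamentals_hz, strictly = TRUE))
    stop("`fundamentals_hz` must be strictly increasing")
  if (is.null(loudness_weights))
    loudness_weights <- loudness_ramp(n)
  if (length(loudness_weights) != n)
    stop("`loudness_weights` must match `fundamentals_hz` in length")
  if (any(loudness_weights <= 0 | loudness_weights > 1))
    stop("`loudness_weights` must lie in (0, 1]")
  if (length(harmonic_multipliers) != length(harmonic_rel_amplitudes))
    stop("harmonic multipliers and amplitudes must have equal length")
  if (length(harmonic_multipliers) &&
      any(harmonic_multipliers != round(harmonic_multipliers) |
          harmonic_multipliers < 2))
    stop("`harmonic_multipliers` must be integers >= 2")
  # highest partial after maximal upward modulation must stay below Nyquist
  kmax <- max(c(1, harmonic_multipliers))
  fmax <- max(fundamentals_hz) * kmax * 2^(abs(pitch_mod_semitones) / 12)
  if (fmax >= audio_sample_rate_hz / 2)
    stop(sprintf("highest partial (%.1f Hz) exceeds Nyquist (%g Hz)",
                 fmax, audio_sample_rate_hz / 2))
  if (fade_s < 0 || output_peak <= 0 || output_peak > 1)
    stop("`fade_s` must be >= 0 and `output_peak` in (0, 1]")
  structure(list(
    fundamentals_hz = as.numeric(fundamentals_hz),
    harmonic_multipliers = as.integer(harmonic_multipliers),
    harmonic_rel_amplitudes = as.numeric(harmonic_rel_amplitudes),
    pitch_mod_semitones = as.numeric(pitch_mod_semitones),
    loudness_weights = as.numeric(loudness_weights),
    audio_sample_rate_hz = as.integer(audio_sample_rate_hz),
    fade_s = as.numeric(fade_s),
    output_peak = as.numeric(output_peak)),
    class = "sonification_config")
}

#' Linear loudness-compensation ramp
#'
#' Per-channel gains falling linearly from `from` (the lowest pitch) to
#' `to` (the highest pitch). This is a deliberately simple stand-in for an
#' equal-loudness contour: subjectively balanced, not a Robinson-Dadson
#' lookup.
#'
#' @param n number of channels.
#' @param from gain of the lowest-pitched channel (default 1.0).
#' @param to gain of the highest-pitched channel (default 0.3).
#' @return Numeric vector of length `n`.
#' @examples
#' loudness_ramp(6) # 1.00 0.86 0.72 0.58 0.44 0.30
#' @export
loudness_ramp <- function(n, from = 1.0, to = 0.3) {
  if (n == 1L) return(from)
  seq(from, to, length.out = n)
}

#' @export
print.sonification_config <- function(x, ...) {
  cat("Polyphonic sonification config\n")
  cat(sprintf("  channels: %d, fundamentals (Hz): %s\n",
              length(x$fundamentals_hz),
              paste(format(x$fundamentals_hz), collapse = ", ")))
  cat(sprintf("  harmonics: k = %s at %s of the fundamental\n",
              paste(x$harmonic_multipliers, collapse = ", "),
              paste(sprintf("%g%%", 100 * x$harmonic_rel_amplitudes),
                    collapse = ", ")))
  cat(sprintf("  pitch modulation: +/-%g semitones at full scale\n",
              x$pitch_mod_semitones))
  cat(sprintf("  loudness weights: %s\n",
              paste(format(round(x$loudness_weights, 2)), collapse = ", ")))
  cat(sprintf("  audio: %d Hz, peak %g, fades %g s\n",
              x$audio_sample_rate_hz, x$output_peak, x$fade_s))
  invisible(x)
}

#' Normalize a voltage channel to [-1, 1]
#'
#' Divides by the maximum absolute value over the whole channel, so the
#' largest deflection (of either sign) maps to full scale. An all-zero
#' channel stays all-zero. Sign- and order-preserving.
#'
#' @param voltages numeric vector (mV), finite, non-empty.
#' @return Numeric vector in `[-1, 1]`.
#' @export
normalize_channel <- function(voltages) {
  if (!length(voltages)) stop("empty channel")
  if (!all(is.finite(voltages))) stop("voltages must be finite")
  m <- max(abs(voltages))
  if (m == 0) return(voltages)
  voltages / m
}

#' Resample a control signal to audio rate
#'
#' Linear interpolation from the ECG sampling rate to the audio rate.
#' Endpoints are preserved and the output never overshoots the input
#' range. Output length is `round(n / ecg_rate_hz * audio_rate_hz)`.
#'
#' @param values normalized control values (at least 2).
#' @param ecg_rate_hz input sampling rate (Hz), below `audio_rate_hz`.
#' @param audio_rate_hz target audio rate (Hz).
#' @return Numeric vector at audio rate.
#' @export
resample_control <- function(values, ecg_rate_hz, audio_rate_hz) {
  if (length(values) < 2L) stop("need at least 2 control samples")
  if (ecg_rate_hz >= audio_rate_hz)
    stop("ECG rate must be below the audio rate")
  n_out <- round(length(values) / ecg_rate_hz * audio_rate_hz)
  stats::approx(x = seq(0, 1, length.out = length(values)), y = values,
                xout = seq(0, 1, length.out = n_out))$y
}

#' Instantaneous oscillator frequency under pitch modulation
#'
#' Exponential (musical) pitch mapping: `f = f0 * 2^(s * v / 12)` with `s`
#' the peak deviation in semitones and `v` the control value in `[-1, 1]`.
#' At the default half-semitone depth, full-scale voltage shifts the pitch
#' by a factor `2^(1/24)`, i.e. about 3%.
#'
#' @param f0 fundamental frequency (Hz), positive.
#' @param v control value(s) in `[-1, 1]`.
#' @param pitch_mod_semitones peak deviation in semitones.
#' @return Frequency in Hz, same length as `v`.
#' @export
instantaneous_frequency <- function(f0, v, pitch_mod_semitones = 0.5) {
  if (any(f0 <= 0)) stop("`f0` must be positive")
  f0 * 2^(pitch_mod_semitones * v / 12)
}

#' Voltage-to-amplitude transfer
#'
#' Linear gain `g(v) = (1 + v) / 2`: the isoelectric baseline (`v = 0`)
#' sounds at half gain so every channel stays audible as a continuous
#' note, full positive deflection is full gain, full negative deflection
#' is silence.
#'
#' @param v control value(s) in `[-1, 1]`.
#' @return Gain in `[0, 1]`.
#' @export
amplitude_gain <- function(v) {
  (1 + v) / 2
}

#' Render one sonified channel
#'
#' Drives a time-variant oscillator at the channel's fundamental with the
#' control signal: the voltage sets the amplitude through
#' [amplitude_gain()] and the pitch through [instantaneous_frequency()].
#' Phase is accumulated sample by sample
#' (`phi[n] = phi[n-1] + 2*pi*f(v[n]) / rate`, starting from 0) so the
#' waveform is continuous with no clicks at control-sample boundaries.
#' The configured harmonics are phase-locked to the fundamental
#' (`sin(k * phi)`) and share its gain envelope; the channel's loudness
#' weight scales the whole rendering.
#'
#' @param control numeric control values in `[-1, 1]` at audio rate.
#' @param config a [sonification_config()].
#' @param channel_index 1-based channel number.
#' @return An [audio_signal()] of the same length as `control`.
#' @export
render_channel <- function(control, config, channel_index) {
  stopifnot(inherits(config, "sonification_config"))
  if (channel_index < 1L || channel_index > length(config$fundamentals_hz))
    stop(sprintf("channel_index %d out of range 1..%d",
                 channel_index, length(config$fundamentals_hz)))
  if (any(abs(control) > 1 + 1e-12)) stop("control values must lie in [-1, 1]")
  f <- instantaneous_frequency(config$fundamentals_hz[channel_index],
                               control, config$pitch_mod_semitones)
  phi <- cumsum(2 * pi * f / config$audio_sample_rate_hz)
  g <- amplitude_gain(control)
  wave <- sin(phi)
  for (j in seq_along(config$harmonic_multipliers)) {
    wave <- wave + config$harmonic_rel_amplitudes[j] *
      sin(config$harmonic_multipliers[j] * phi)
  }
  samples <- config$loudness_weights[channel_index] * g * wave
  # headroom: fundamental + harmonics can top 1 slightly before mixing
  structure(list(samples = samples,
                 sample_rate_hz = config$audio_sample_rate_hz),
            class = "audio_signal")
}

#' Mix rendered channels into one audio signal
#'
#' Sample-wise sum of all channels, peak-normalized to
#' `config$output_peak` (a silent sum is left silent), then raised-cosine
#' fades of `config$fade_s` applied at both ends.
#'
#' @param channels list of [audio_signal()] objects of equal length and
#'   rate.
#' @param config a [sonification_config()].
#' @return An [audio_signal()].
#' @export
mix_channels <- function(channels, config) {
  stopifnot(inherits(config, "sonification_config"), length(channels) >= 1L)
  lens <- vapply(channels, function(ch) length(ch$samples), 0L)
  rates <- vapply(channels, function(ch) ch$sample_rate_hz, 0L)
  if (length(unique(lens)) != 1L || length(unique(rates)) != 1L)
    stop("channels differ in length or sample rate")
  s <- Reduce(`+`, lapply(channels, `[[`, "samples"))
  peak <- max(abs(s))
  if (peak > 0) s <- s * (config$output_peak / peak)
  s <- apply_fades(s, rates[1L], config$fade_s)
  audio_signal(s, rates[1L])
}

# raised-cosine (half-Hann) fade-in/out over fade_s seconds at each end
apply_fades <- function(samples, rate, fade_s) {
  nf <- min(floor(fade_s * rate), floor(length(samples) / 2))
  if (nf < 1L) return(samples)
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nf)))
  samples[seq_len(nf)] <- samples[seq_len(nf)] * ramp
  tail_idx <- length(samples) - seq_len(nf) + 1L
  samples[tail_idx] <- samples[tail_idx] * ramp
  samples
}

#' Sonify a multi-lead ECG record
#'
#' The full polyphonic pipeline: each lead is max-abs normalized
#' ([normalize_channel()]), linearly resampled to audio rate
#' ([resample_control()]), rendered as a voltage-modulated oscillator at
#' its assigned note ([render_channel()]), and the channels are summed and
#' normalized ([mix_channels()]). Channel order defines pitch order: lead
#' 1 gets the lowest note. The result is a continuous stream of as many
#' simultaneous notes as the record has leads; the whole pipeline is
#' deterministic.
#'
#' @param record an [ecg_record()] with exactly as many leads as
#'   `config$fundamentals_hz` has notes.
#' @param config a [sonification_config()].
#' @return An [audio_signal()] whose duration equals the record duration
#'   to within one audio sample.
#' @examples
#' rec <- generate_ecg(synthetic_ecg_spec("normal", seed = 1, duration_s = 2))
#' aud <- sonify(rec, sonification_config())
#' aud
#' @export
sonify <- function(record, config = sonification_config()) {
  stopifnot(inherits(record, "ecg_record"))
  n_leads <- length(record$lead_names)
  n_notes <- length(config$fundamentals_hz)
  if (n_leads != n_notes)
    stop(sprintf("record has %d leads but config has %d notes; counts must match",
                 n_leads, n_notes))
  channels <- lapply(seq_len(n_leads), function(i) {
    v <- normalize_channel(record$voltages[, i])
    ctrl <- resample_control(v, record$sample_rate_hz,
                             config$audio_sample_rate_hz)
    render_channel(ctrl, config, i)
  })
  mix_channels(channels, config)
}
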