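test_that("normalize_channel is max-abs scaling with safe zero handling", {
  expect_equal(normalize_channel(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(normalize_channel(c(-2, 1)), c(-1, 0.5))
  expect_error(normalize_channel(c(1, NA)), "finite")
  expect_error(normalize_channel(numeric(0)), "empty")
  for (seed in 1:5) {
    set.seed(seed)
    x <- stats::rnorm(200)
    y <- normalize_channel(x)
    expect_equal(max(abs(y)), 1)
    expect_equal(sign(y), sign(x))          # sign-preserving
    expect_equal(order(y), order(x))        # order-preserving
  }
})

test_that("resample_control interpolates linearly without overshoot", {
  out <- resample_control(c(0.5, 0.5), 2, 100)
  expect_length(out, 100)
  expect_true(all(out == 0.5))

  ramp <- resample_control(c(0, 1), 2, 1000)
  expect_equal(ramp[1], 0)
  expect_equal(ramp[length(ramp)], 1)
  expect_equal(ramp[round(length(ramp) / 2)], 0.5, tolerance = 2e-3)

  set.seed(4)
  x <- stats::runif(257, -1, 1)
  y <- resample_control(x, 257, 44100)
  expect_length(y, round(257 / 257 * 44100))
  expect_gte(min(y), min(x))
  expect_lte(max(y), max(x))
  expect_error(resample_control(0.5, 257, 44100), "at least 2")
  expect_error(resample_control(c(0, 1), 500, 257), "below")
})

test_that("pitch modulation follows the exponential semitone law", {
  expect_equal(instantaneous_frequency(146.83, 0), 146.83)
  # full-scale deviation at the half-semitone default is 2^(1/24), about +3%
  expect_equal(instantaneous_frequency(200, 1, 0.5) / 200, 2^(1 / 24))
  expect_equal(2^(1 / 24), 1.0293, tolerance = 1e-4)
  # geometric symmetry: up and down full-scale deviations cancel
  up <- instantaneous_frequency(123, 1, 0.5) / 123
  down <- instantaneous_frequency(123, -1, 0.5) / 123
  expect_equal(up * down, 1)
  v <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(instantaneous_frequency(100, v, 0.5)) > 0))
  expect_error(instantaneous_frequency(-1, 0), "positive")
})

test_that("amplitude transfer keeps the baseline audible at half gain", {
  expect_equal(amplitude_gain(0), 0.5)
  expect_equal(amplitude_gain(1), 1)
  expect_equal(amplitude_gain(-1), 0)
  v <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(amplitude_gain(v)) > 0))
})

test_that("render_channel matches the naive per-sample synthesis oracle", {
  config <- fast_config()
  set.seed(21)
  # slowly varying control, 1 s
  ctrl <- resample_control(stats::runif(9, -1, 1), 8, 8000)
  for (ch in c(1L, 4L, 6L)) {
    got <- render_channel(ctrl, config, ch)
    want <- naive_render(ctrl, config, ch)
    expect_lt(max(abs(got$samples - want)), 1e-9)
  }
})

test_that("render_channel honours gain, loudness weight and bounds", {
  config <- fast_config()
  silent <- render_channel(rep(-1, 4000), config, 1)
  expect_true(all(silent$samples == 0))
  expect_error(render_channel(rep(0, 10), config, 7), "out of range")
  expect_error(render_channel(c(0, 2), config, 1), "\\[-1, 1\\]")
  # RMS under identical control scales as the loudness ramp (1.00 .. 0.30)
  ctrl <- rep(0, 8000)
  r <- vapply(1:6, function(ch) rms(render_channel(ctrl, config, ch)$samples), 0)
  expect_equal(r / r[1], config$loudness_weights, tolerance = 1e-2)
})

test_that("phase accumulates continuously across control jumps", {
  config <- fast_config()
  # worst case: a hard control step from -1 to +1 mid-buffer
  ctrl <- c(rep(-0.99, 4000), rep(1, 4000))
  audio <- render_channel(ctrl, config, 6)
  fmax <- max(instantaneous_frequency(config$fundamentals_hz[6], 1, 0.5)) *
    max(config$harmonic_multipliers)
  # discrete derivative of the waveform bounded by amplitude * 2*pi*f/fs
  max_step <- (1 + sum(config$harmonic_rel_amplitudes)) *
    2 * pi * fmax / config$audio_sample_rate_hz
  expect_lt(max(abs(diff(audio$samples))), max_step * 1.1)
})

test_that("mixing normalizes the peak, fades the edges and stays linear", {
  config <- fast_config()
  set.seed(31)
  chans <- lapply(1:6, function(ch)
    render_channel(resample_control(stats::runif(9, -1, 1), 8, 8000),
                   config, ch))
  mixed <- mix_channels(chans, config)
  expect_equal(max(abs(mixed$samples)), config$output_peak, tolerance = 1e-9)
  expect_true(all(abs(mixed$samples) <= 1))

  # linearity: mix equals the scaled sum of the individual channels
  raw_sum <- Reduce(`+`, lapply(chans, `[[`, "samples"))
  scale <- config$output_peak / max(abs(raw_sum))
  inner <- 400:7600  # away from the fade regions
  expect_equal(mixed$samples[inner], (raw_sum * scale)[inner], tolerance = 1e-12)

  # single channel: that channel scaled to output_peak
  one <- mix_channels(chans[1], config)
  expect_equal(one$samples[inner],
               (chans[[1]]$samples * config$output_peak /
                  max(abs(chans[[1]]$samples)))[inner], tolerance = 1e-12)

  # degenerate: all-silent input stays silent, no division by zero
  silent <- lapply(1:2, function(i)
    structure(list(samples = numeric(8000), sample_rate_hz = 8000L),
              class = "audio_signal"))
  expect_true(all(mix_channels(silent, config)$samples == 0))

  short <- structure(list(samples = numeric(100), sample_rate_hz = 8000L),
                     class = "audio_signal")
  expect_error(mix_channels(list(chans[[1]], short), config), "length")
})

test_that("sonify produces duration-matched, deterministic audio", {
  rec <- generate_ecg(synthetic_ecg_spec("normal", seed = 5))
  config <- sonification_config()
  audio <- sonify(rec, config)
  expect_equal(length(audio$samples), 441000)  # 10 s at 44100 Hz
  expect_equal(audio$sample_rate_hz, 44100L)
  audio2 <- sonify(rec, config)
  expect_identical(audio$samples, audio2$samples)

  bad <- select_leads(rec, c("I", "II"))
  expect_error(sonify(bad, config), "2 leads.*6 notes")
})

test_that("a single active lead dominates the mix at its own pitch", {
  config <- fast_config()
  v <- matrix(0, 514, 6)
  set.seed(9)
  v[, 3] <- stats::rnorm(514, sd = 0.2)
  # other leads all-zero: normalize keeps them zero, but gain(0) = 0.5 still
  # sounds them; make lead 3 strongly modulated and check its pitch leads
  rec <- ecg_record(v, 257, c("I", "II", "III", "aVR", "aVL", "aVF"))
  audio <- sonify(rec, config)
  p <- fft_peak(audio, config$fundamentals_hz[3] * c(0.94, 1.06))
  expect_true(p$found)
  expect_equal(p$frequency_hz, config$fundamentals_hz[3], tolerance = 0.05)
})

test_that("sonification_config enforces its invariants", {
  expect_error(sonification_config(fundamentals_hz = c(220, 146.83)),
               "increasing")
  expect_error(sonification_config(fundamentals_hz = c(100, 15000),
                                   audio_sample_rate_hz = 44100), "Nyquist")
  expect_error(sonification_config(harmonic_multipliers = c(3, 4),
                                   harmonic_rel_amplitudes = 0.15), "equal length")
  expect_error(sonification_config(loudness_weights = rep(2, 6)), "\\(0, 1\\]")
  cfg <- sonification_config()
  expect_false(2 %in% cfg$harmonic_multipliers)  # omitted on purpose
  expect_equal(cfg$loudness_weights, c(1.00, 0.86, 0.72, 0.58, 0.44, 0.30))
})

test_that("WAV files round-trip through both encodings", {
  set.seed(12)
  audio <- audio_signal(stats::runif(4000, -0.9, 0.9), 8000)
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio, p16)
  back <- read_wav(p16)
  expect_equal(back$sample_rate_hz, 8000L)
  expect_equal(back$samples, audio$samples, tolerance = 1 / 32767)

  pf <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio, pf, bit_depth = "float32")
  backf <- read_wav(pf)
  expect_equal(backf$samples, audio$samples, tolerance = 1e-7)
})
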