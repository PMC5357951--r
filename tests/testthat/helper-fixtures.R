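# Shared fixtures: small records, controls and the naive synthesis oracle.

tiny_record <- function(n = 100, leads = c("I", "II"), rate = 257,
                        seed = 11) {
  set.seed(seed)
  ecg_record(matrix(stats::rnorm(n * length(leads)), ncol = length(leads)),
             rate, leads)
}

# short config: low audio rate keeps unit tests fast where spectral
# resolution is not at stake
fast_config <- function(...) {
  sonification_config(audio_sample_rate_hz = 8000,
                      fundamentals_hz = c(146.83, 174.61, 220.00,
                                          293.67, 349.23, 440.00), ...)
}

# Independent per-sample additive-synthesis oracle: re-derives the whole
# rendering with an explicit scalar loop (no cumsum, no vectorization).
naive_render <- function(control, config, channel_index) {
  f0 <- config$fundamentals_hz[channel_index]
  w <- config$loudness_weights[channel_index]
  fs <- config$audio_sample_rate_hz
  out <- numeric(length(control))
  phi <- 0
  for (n in seq_along(control)) {
    f <- f0 * 2^(config$pitch_mod_semitones * control[n] / 12)
    phi <- phi + 2 * pi * f / fs
    g <- (1 + control[n]) / 2
    val <- sin(phi)
    for (j in seq_along(config$harmonic_multipliers))
      val <- val + config$harmonic_rel_amplitudes[j] *
        sin(config$harmonic_multipliers[j] * phi)
    out[n] <- w * g * val
  }
  out
}

rms <- function(x) sqrt(mean(x^2))

responses_fixture <- function() {
  read_responses(system.file("extdata", "synthetic_observer_responses.csv",
                             package = "ecgsonify"))
}

# minimal hand-built response table: n_correct out of 4 samples per observer
small_responses <- function(correct_per_observer,
                            groups = rep(1L, length(correct_per_observer))) {
  cls <- study_classes()
  rows <- do.call(rbind, lapply(seq_along(correct_per_observer), function(i) {
    ok <- seq_len(4) <= correct_per_observer[i]
    data.frame(observer_id = sprintf("ob%02d", i), group = groups[i],
               musician = FALSE, sample_id = sprintf("s%d", 1:4),
               true_class = cls,
               assigned_class = ifelse(ok, cls, cls[c(2, 3, 4, 1)]))
  }))
  observer_responses(rows)
}
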