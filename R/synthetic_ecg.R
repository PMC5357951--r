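#' Gaussian PQRST beat template
#'
#' A single heartbeat modelled as a sum of five Gaussian waves (P, Q, R,
#' S, T), each with a center offset from the beat onset (s), a width
#' (Gaussian sd, s) and an amplitude (mV). The defaults give an ECG-like
#' morphology at 75 bpm. `st_offset_mv` shifts the baseline between the
#' end of the S wave and the onset of the T wave (the ST segment); it is 0
#' for a normal beat and positive for ST elevation.
#'
#' @param centers_s named numeric vector of wave centers, ordered
#'   P < Q < R < S < T.
#' @param widths_s named numeric vector of Gaussian sds (s), all positive.
#' @param amplitudes_mv named numeric vector of wave amplitudes (mV).
#' @param st_offset_mv ST-segment baseline shift (mV), default 0.
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(
    centers_s = c(P = 0.10, Q = 0.216, R = 0.24, S = 0.264, T = 0.45),
    widths_s = c(P = 0.025, Q = 0.008, R = 0.012, S = 0.008, T = 0.04),
    amplitudes_mv = c(P = 0.15, Q = -0.10, R = 1.00, S = -0.25, T = 0.35),
    st_offset_mv = 0) {
  waves <- c("P", "Q", "R", "S", "T")
  if (!identical(names(centers_s), waves) ||
      !identical(names(widths_s), waves) ||
      !identical(names(amplitudes_mv), waves))
    stop("centers, widths and amplitudes must be named P, Q, R, S, T")
  if (any(widths_s <= 0)) stop("wave widths must be positive")
  if (is.unsorted(centers_s, strictly = TRUE))
    stop("wave centers must be ordered P < Q < R < S < T")
  structure(list(centers_s = centers_s, widths_s = widths_s,
                 amplitudes_mv = amplitudes_mv,
                 st_offset_mv = st_offset_mv),
            class = "beat_template")
}

# ST window of a template: from 3 sd past the S center to 3 sd before the
# T center, i.e. the flat segment between the two waves.
st_window <- function(template) {
  c(template$centers_s[["S"]] + 3 * template$widths_s[["S"]],
    template$centers_s[["T"]] - 3 * template$widths_s[["T"]])
}

#' Specification of a synthetic six-lead ECG
#'
#' Parameters for the synthetic generator: pathology class, rhythm, noise
#' and the frontal-plane geometry (lead angles on the Cabrera circle and
#' the mean electrical axis). All randomness is driven by `seed`.
#'
#' @param pathology one of `"normal"`, `"stemi"`, `"pvc"`, `"bigeminy"`,
#'   `"afib"`.
#' @param heart_rate_bpm mean heart rate (default 75).
#' @param duration_s record duration in seconds (default 10).
#' @param sample_rate_hz ECG sampling rate in Hz (default 257).
#' @param noise_sd_mv sd of additive Gaussian measurement noise in mV
#'   (default 0.02).
#' @param seed integer seed; identical specs give identical records.
#' @param lead_angles_deg named angles of the six frontal leads on the
#'   Cabrera circle, degrees in (-180, 180].
#' @param axis_deg mean electrical axis in degrees (default 60, a normal
#'   axis).
#' @param st_offset_mv ST elevation applied for the `"stemi"` class (mV,
#'   default 0.3).
#' @param template a [beat_template()] for the normal beat morphology.
#' @return An object of class `synthetic_ecg_spec`.
#' @export
synthetic_ecg_spec <- function(
    pathology = c("normal", "stemi", "pvc", "bigeminy", "afib"),
    heart_rate_bpm = 75, duration_s = 10, sample_rate_hz = 257,
    noise_sd_mv = 0.02, seed = 1L,
    lead_angles_deg = c(I = 0, II = 60, III = 120,
                        aVR = -150, aVL = -30, aVF = 90),
    axis_deg = 60, st_offset_mv = 0.3, template = beat_template()) {
  pathology <- match.arg(pathology)
  if (heart_rate_bpm <= 0 || duration_s <= 0 || sample_rate_hz <= 0)
    stop("rate and duration parameters must be positive")
  if (duration_s * sample_rate_hz < 2)
    stop("spec must yield at least 2 samples")
  if (noise_sd_mv < 0) stop("`noise_sd_mv` must be >= 0")
  if (any(lead_angles_deg <= -180 | lead_angles_deg > 180))
    stop("lead angles must lie in (-180, 180]")
  if (is.null(names(lead_angles_deg)))
    stop("`lead_angles_deg` must be named by lead")
  structure(list(
    pathology = pathology, heart_rate_bpm = heart_rate_bpm,
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    noise_sd_mv = noise_sd_mv, seed = as.integer(seed),
    lead_angles_deg = lead_angles_deg, axis_deg = axis_deg,
    st_offset_mv = st_offset_mv, template = template),
    class = "synthetic_ecg_spec")
}

# run `expr` under a private RNG stream, restoring global RNG state after
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate the beat-to-beat rhythm for a pathology class
#'
#' Produces RR intervals and beat types covering the record duration:
#' \describe{
#'   \item{normal / stemi}{constant RR = 60 / heart rate with up to 2%
#'     uniform jitter.}
#'   \item{pvc}{the normal rhythm with isolated premature ventricular
#'     beats (about 10% of beats, at least one): a PVC follows its
#'     preceding normal beat after a coupling interval of 0.6 RR and is
#'     followed by a full compensatory pause, so coupling + pause = 2 RR.}
#'   \item{bigeminy}{strict normal/PVC alternation, every PVC with the
#'     same coupling/pause geometry.}
#'   \item{afib}{RR drawn independently from a log-normal with mean
#'     60 / heart rate and coefficient of variation 0.25 — the
#'     "irregularly irregular" rhythm; no two consecutive intervals are
#'     equal.}
#' }
#' Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_ecg_spec()].
#' @return An object of class `rhythm_model` with fields `rr_intervals_s`
#'   (interval from beat i to beat i+1) and `beat_types` (`"normal"` or
#'   `"pvc"` per beat).
#' @export
make_rhythm <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ecg_spec"))
  rr0 <- 60 / spec$heart_rate_bpm
  n <- ceiling(spec$duration_s / rr0) + 2L
  rhythm <- with_seed(spec$seed, {
    switch(spec$pathology,
      normal = ,
      stemi = {
        rr <- rr0 * (1 + stats::runif(n, -0.02, 0.02))
        list(rr = rr, types = rep("normal", n))
      },
      pvc = {
        rr <- rr0 * (1 + stats::runif(n, -0.02, 0.02))
        types <- rep("normal", n)
        n_pvc <- max(1L, round(0.1 * n))
        # isolated PVCs: interior positions, no two adjacent
        pos <- integer(0)
        candidates <- 2:(n - 1L)
        for (k in seq_len(n_pvc)) {
          if (!length(candidates)) break
          p <- if (length(candidates) == 1L) candidates
               else sample(candidates, 1L)
          pos <- c(pos, p)
          candidates <- setdiff(candidates, (p - 1L):(p + 1L))
        }
        for (p in pos) {
          rr[p - 1L] <- 0.6 * rr0  # coupling interval into the PVC
          rr[p] <- 1.4 * rr0       # compensatory pause after it
          types[p] <- "pvc"
        }
        list(rr = rr, types = types)
      },
      bigeminy = {
        types <- rep(c("normal", "pvc"), length.out = n)
        rr <- ifelse(types == "normal", 0.6 * rr0, 1.4 * rr0)
        list(rr = rr, types = types)
      },
      afib = {
        cv <- 0.25
        sdlog <- sqrt(log(1 + cv^2))
        meanlog <- log(rr0) - sdlog^2 / 2
        n <- n + 4L  # irregular rhythm may need more beats to cover
        rr <- stats::rlnorm(n, meanlog, sdlog)
        while (any(diff(rr) == 0))
          rr[which(diff(rr) == 0) + 1L] <- stats::rlnorm(sum(diff(rr) == 0),
                                                         meanlog, sdlog)
        list(rr = rr, types = rep("normal", n))
      })
  })
  # extend so the cumulative intervals always cover the duration
  while (sum(rhythm$rr) < spec$duration_s) {
    rhythm$rr <- c(rhythm$rr, rr0)
    rhythm$types <- c(rhythm$types, "normal")
  }
  structure(list(rr_intervals_s = rhythm$rr, beat_types = rhythm$types),
            class = "rhythm_model")
}

#' Render the scalar cardiac source signal
#'
#' Places one beat template at each cumulative-RR onset and sums them.
#' PVC beats use the textbook wide-QRS variant: QRS width tripled, QRS
#' amplitude times 1.5, no P wave. For the `"stemi"` class the configured
#' ST offset is added between the S and T waves of every beat; for
#' `"afib"` P waves are dropped everywhere and band-limited 4-9 Hz
#' fibrillatory noise (sd 0.05 mV) replaces them. Additive Gaussian noise
#' of `spec$noise_sd_mv` is applied throughout. Deterministic given
#' `spec$seed`.
#'
#' @param rhythm a [make_rhythm()] result.
#' @param template a [beat_template()].
#' @param spec a [synthetic_ecg_spec()].
#' @return Numeric vector of length `duration_s * sample_rate_hz` (mV).
#' @export
render_dipole <- function(rhythm, template, spec) {
  stopifnot(inherits(rhythm, "rhythm_model"),
            inherits(template, "beat_template"),
            inherits(spec, "synthetic_ecg_spec"))
  n <- round(spec$duration_s * spec$sample_rate_hz)
  t <- (seq_len(n) - 1L) / spec$sample_rate_hz
  onsets <- cumsum(c(0, rhythm$rr_intervals_s))[seq_along(rhythm$beat_types)]
  x <- numeric(n)
  stw <- st_window(template)
  st_off <- if (spec$pathology == "stemi") spec$st_offset_mv
            else template$st_offset_mv
  for (i in seq_along(onsets)) {
    o <- onsets[i]
    if (o > spec$duration_s) break
    is_pvc <- rhythm$beat_types[i] == "pvc"
    for (w in c("P", "Q", "R", "S", "T")) {
      if (w == "P" && (is_pvc || spec$pathology == "afib")) next
      width <- template$widths_s[[w]]
      amp <- template$amplitudes_mv[[w]]
      if (is_pvc && w %in% c("Q", "R", "S")) {
        width <- width * 3
        amp <- amp * 1.5
      }
      x <- x + amp * exp(-(t - o - template$centers_s[[w]])^2 / (2 * width^2))
    }
    if (st_off != 0 && !is_pvc) {
      idx <- t >= o + stw[1L] & t <= o + stw[2L]
      x[idx] <- x[idx] + st_off
    }
  }
  with_seed(spec$seed + 1L, {
    if (spec$pathology == "afib") {
      # fibrillatory baseline: white noise band-passed to 4-9 Hz
      bf <- signal::butter(2, c(4, 9) / (spec$sample_rate_hz / 2),
                           type = "pass")
      fib <- signal::filtfilt(bf, stats::rnorm(n))
      x <- x + fib * (0.05 / stats::sd(fib))
    }
    if (spec$noise_sd_mv > 0)
      x <- x + stats::rnorm(n, sd = spec$noise_sd_mv)
    x
  })
}

#' Project the cardiac source onto the six frontal-plane leads
#'
#' Single-dipole model: each lead sees the scalar source scaled by the
#' cosine of the angle between that lead's Cabrera-circle direction and
#' the mean electrical axis, `lead_i(t) = dipole(t) * cos(angle_i - axis)`.
#' A lead aligned with the axis reproduces the source exactly; a lead at
#' 90 degrees to it is flat.
#'
#' @param dipole numeric source signal at `spec$sample_rate_hz` (mV).
#' @param spec a [synthetic_ecg_spec()].
#' @return An [ecg_record()] with the leads of `spec$lead_angles_deg`, in
#'   that order.
#' @export
project_leads <- function(dipole, spec) {
  stopifnot(inherits(spec, "synthetic_ecg_spec"))
  proj <- cos((spec$lead_angles_deg - spec$axis_deg) * pi / 180)
  v <- outer(dipole, proj)
  ecg_record(v, spec$sample_rate_hz, names(spec$lead_angles_deg))
}

#' Generate a synthetic six-lead ECG record
#'
#' Composes [make_rhythm()], [render_dipole()] and [project_leads()] for
#' the requested pathology class. Reproducible: identical specs (including
#' the seed) give identical records.
#'
#' @param spec a [synthetic_ecg_spec()].
#' @return An [ecg_record()] with six frontal-plane leads at the spec's
#'   duration and sampling rate.
#' @examples
#' rec <- generate_ecg(synthetic_ecg_spec("bigeminy", seed = 7))
#' rec
#' @export
generate_ecg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_ecg_spec"))
  template <- spec$template
  rhythm <- make_rhythm(spec)
  dipole <- render_dipole(rhythm, template, spec)
  project_leads(dipole, spec)
}
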