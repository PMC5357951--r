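---
title: "Polyphonic ECG sonification: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyphonic ECG sonification: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgsonify)
```

## The sonification model

ecgsonify implements a parameter-mapping sonification of six-channel
frontal-plane ECG. Each lead is assigned a fixed musical note and drives
a time-variant oscillator; the lead's voltage continuously controls the
oscillator's amplitude and pitch. Six oscillators sound simultaneously,
so a trained listener can attend to individual leads inside the chord —
the design goal is that rhythm disturbances (a premature beat, an
irregularly irregular pulse) and morphology changes (an elevated ST
segment) become audible events.

For channel $i$ with fundamental $f_{0,i}$ and normalized voltage
$v_i(t) \in [-1, 1]$, a rendered sample at audio rate $f_s$ is

$$
y_i[n] = w_i \, g(v_i[n]) \Big( \sin \varphi_i[n]
        + \sum_{k \in \{3,4,5\}} a_k \sin(k\,\varphi_i[n]) \Big),
\qquad
\varphi_i[n] = \varphi_i[n-1] + \frac{2\pi f_i(v_i[n])}{f_s},
$$

with $g(v) = (1+v)/2$, $f_i(v) = f_{0,i}\,2^{s v / 12}$,
$a_{3,4,5} = 0.15, 0.05, 0.05$, $s = 0.5$ semitones, and $w_i$ the
loudness weight. The mix is the sample-wise sum over channels,
peak-normalized and edge-faded.

Assumptions worth making explicit:

- **Normalization scope.** Each channel is scaled by its own max-abs
  over the whole record, so relative amplitude information *between*
  leads is discarded in favour of keeping every lead audible. Within a
  lead, relative deflection sizes are preserved.
- **No preprocessing.** No baseline-wander or mains-hum filtering is
  applied before mapping; a drifting baseline will audibly drift the
  loudness and pitch of the affected channel. Whether filtering helps is
  a perceptual question this package does not answer.
- **Deterministic pipeline.** There is no randomness anywhere between
  record and WAV; identical inputs are bit-identical outputs.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `fundamentals_hz` | 146.83 … 440.00 | Hz | D minor over two octaves; consonant, and the two-octave spread separates the streams |
| `harmonic_multipliers` | 3, 4, 5 | — | adds timbre; **2 is omitted** because channels 4–6 sit exactly one octave above channels 1–3, and an octave partial would mask them |
| `harmonic_rel_amplitudes` | 0.15, 0.05, 0.05 | fraction | gentle brightness without masking |
| `pitch_mod_semitones` | 0.5 | semitones | full-scale voltage shifts pitch by $2^{1/24} \approx 1.0293$, a ±3% variation — audible but not melodic |
| `loudness_weights` | 1.00 → 0.30 linear | fraction | compensates the ear's greater sensitivity at higher frequencies; a deliberate linear ramp, not an equal-loudness contour |
| `audio_sample_rate_hz` | 44100 | Hz | CD rate; all partials stay far below Nyquist |
| `fade_s`, `output_peak` | 0.005, 0.9 | s, fraction | suppress onset/offset clicks and leave headroom against clipping |

Design choices where the design was genuinely open:

- **Amplitude transfer.** Voltage "maps to amplitude" admits many
  curves; we use the affine $g(v) = (1+v)/2$ so that the isoelectric
  baseline sounds at half gain — the six-note chord is continuous, and
  both polarities of deflection are audible (louder/up-pitched vs
  softer/down-pitched). A consequence: at $v = -1$ the channel is
  momentarily silent, so no pitch is defined there.
- **Pitch law.** Exponential in semitones rather than linear in Hz; at
  half a semitone the two differ by under 0.05%, but the semitone form
  is exact in musical-pitch terms and symmetric as a frequency *ratio*.
- **Harmonics phase-locked** to the fundamental ($k\varphi$) and sharing
  its gain envelope: one coherent timbre per channel rather than
  independently drifting partials.
- **Lead-to-note assignment** defaults to dataset order (I, II, III,
  aVR, aVL, aVF) mapped to ascending pitch. An ordering by Cabrera angle
  is equally defensible; the assignment is just the column order of the
  record passed to `sonify()`, so callers can reorder with
  `select_leads()`.
- **Phase starts at 0** for every channel: relative phase between steady
  tones is perceptually irrelevant, and a fixed origin keeps renders
  reproducible.

## The synthetic generator

`generate_ecg()` exists so the sonifier and the statistics have a fully
controlled, downloadable-data-free test bed. It emulates:

- a **Gaussian P-Q-R-S-T beat**: five Gaussians (centers, widths,
  amplitudes in `beat_template()`), the simplest morphology with a
  controllable ST segment and QRS width;
- a **per-class rhythm model**: normal/STEMI at constant RR with ≤2%
  jitter; PVC with isolated premature beats at a 0.6·RR coupling
  interval and a full compensatory pause (coupling + pause = 2·RR);
  bigeminy as strict normal/PVC alternation; atrial fibrillation with
  i.i.d. log-normal RR (CV 0.25) — the "irregularly irregular" pulse —
  plus absent P waves and 4–9 Hz band-limited fibrillatory baseline
  noise (sd 0.05 mV);
- a **PVC morphology** with QRS width ×3, QRS amplitude ×1.5 and no P
  wave — the textbook features, each individually assertable;
- a **single-dipole frontal-plane projection**: every lead is the scalar
  source times the cosine of the angle between the lead direction on the
  Cabrera circle and the mean electrical axis (default 60°). This keeps
  closed-form lead ratios testable (e.g. with default angles, leads I
  and III see identical projections, and aVL at axis+90° is flat).

What it does **not** emulate: vectorcardiographic loop rotation (every
lead is a scalar multiple of the same source, which real leads are not),
heart-rate-variability spectra, respiratory modulation, electrode noise
beyond white Gaussian, ischemia morphologies beyond a boxcar ST shift,
or any specific database record. Tests passing on synthetic data
therefore validate the *pipeline* — mapping laws, spectra, rhythm
statistics — not clinical realism.

Defaults (75 bpm, 10 s, 257 Hz, 0.02 mV noise) mirror the study
conditions the sonifier targets: 10-second six-lead segments at 257 Hz.

## Measurement utilities and numerical choices

`fft_peak()` applies a Hann window and takes the maximum-magnitude bin
in the requested band, then refines in two stages: 3-bin parabolic
interpolation, followed by a second parabolic fit on the *continuous*
windowed spectrum (three exact DTFT evaluations a quarter-bin apart).
The second stage matters: plain parabolic interpolation of Hann-window
magnitudes carries a scalloping bias of up to a few percent in the peak
*height*, which would corrupt harmonic-ratio measurements; evaluating
the DTFT at the refined frequency removes it. Frequencies come out
accurate to well under 0.1 Hz on 10 s windows, magnitudes to a relative
error below $10^{-4}$. Silence and empty bands return an explicit
"no peak" value rather than an error, so pitch tracks over silent frames
are `NA`. Magnitudes are linear amplitude, never dB, because the design's
harmonic percentages are linear amplitude fractions.

Other numerical details: control signals are linearly interpolated from
257 Hz to audio rate (the control rate is far above envelope-perception
bandwidth, and linear interpolation cannot overshoot); phase is
accumulated, never reset, so there are no click transients; mixing
normalizes by the true peak with a guard for all-silent input; WFDB
storage quantizes voltages to 1/gain mV (default 1/2000) in 16-bit
integers, and the round-trip error bound of half a quantization step is
asserted in the tests.

## Study statistics

`study_eval` computes per-observer correct-classification rates, group
means ± sample standard deviations (n−1), the 4×4 confusion matrix with
per-class rates, the fraction of observers strictly above an accuracy
threshold, and one-tailed two-sample t-tests. "Student's t-test" is read
as the pooled-variance form (Welch available via `welch = TRUE`);
`one_tailed_t_summary()` applies the same test to published (n, mean, sd)
summaries. "Over 90%" uses strict inequality — with 12 samples that
means at least 11 correct. Display rounds to integer percent; all
computation is on fractions.

The packaged response sheet
(`inst/extdata/synthetic_observer_responses.csv`) is **synthetic**: a
constructed 22-observer × 12-sample table whose group summaries
(78 ± 22%, 68 ± 18%, 50 ± 30%), >90% fraction (6 of 22), top-performing
class (PVC, 89%) and group-1 vs group-3 contrast (one-tailed pooled
p = 0.028) sit at the values a study of this design would report. It
exercises and demonstrates the statistics; it contains no human data.

## Problem sizes and limitations

The test suite renders seconds-long audio (10 s at 44.1 kHz for
spectral checks, 1 s for the sample-by-sample oracle comparison) and
generates 10-second ECGs — sizes chosen because every quantity being
checked (sub-0.1 Hz peak accuracy, RR statistics over ~13 beats) is
already stable there.

Known limitations: no real-time/streaming rendering; no stereo or
spatialization; no psychoacoustic loudness model (the linear ramp is a
deliberate simplification); WFDB support covers format 16 with mV units
only — other storage formats and annotation files are out of scope; and
the generator's realism caveats above.
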