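---
title: "Analyzing EEG responses to rough vocalizations across sleep and wakefulness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing EEG responses to rough vocalizations across sleep and wakefulness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalsleep)
```

## The scientific problem

Screamed vocalizations differ from neutral ones chiefly in *roughness*:
energy in fast amplitude modulations of the waveform envelope, in the
30–150 Hz range. Roughness is a salience cue, and an interesting question is
whether the sleeping brain still privileges rough sounds. The experimental
design this package supports presents pitch-matched screamed and neutral
vocalizations during wakefulness and overnight sleep while recording
polysomnographic EEG, and asks three questions:

1. Do rough vocalizations evoke more *phase-consistent* low-frequency
   responses (inter-trial phase coherence, ITPC, in the theta band)?
2. Do they evoke more *induced power* in the signatures of NREM sleep —
   spindle-band (sigma, 12–15 Hz) and slow-wave (delta, 1–4 Hz) activity?
3. Is that modulation attributable to roughness specifically, rather than
   pitch, at the single-trial level?

`vocalsleep` implements the full measurement chain — acoustic feature
extraction, EEG preprocessing, Morlet time–frequency decomposition, ITPC,
single-trial regression, and cluster-based permutation inference — together
with a synthetic stimulus and polysomnography generator so that every stage
is testable against known ground truth without access to recorded data.

## Acoustic features

**Roughness** is measured from the modulation power spectrum (MPS): a short
window spectrogram (10 ms Hann windows, 800 Hz frame rate, so envelope
modulations up to 150 Hz and beyond are resolvable) is log-compressed with a
60 dB floor, mean-removed, and Fourier-transformed in 2-D. Roughness is the
base-10 log of the mean modulation power in the 30–150 Hz temporal band
(both spectral signs pooled) divided by total modulation power. Two
numerical choices matter:

* *Log compression with a 60 dB floor.* Compression makes the measure
  gain-invariant (a gain change adds a constant that mean removal cancels).
  The floor keeps spectral-leakage wiggles of near-silent spectrogram cells
  from exploding in the log domain. Compression is nonlinear, so a
  sinusoidally modulated tone contributes energy at exact harmonics of its
  modulation rate as well as at the rate itself; the uncompressed transform
  concentrates ≥ 90 % of in-band energy within ±5 Hz of the true rate.
* *Normalization by total modulation power*, which makes the arbitrary-unit
  scale comparable across clips. Absolute values on other normalizations
  differ by a constant offset; only orderings and differences are
  interpretable across implementations.

**Fundamental frequency** uses the cumulative-mean-normalized difference
function (the YIN family), searching 40–1500 Hz to cover the high
fundamentals of screams, with parabolic refinement and a sub-multiple
(octave-error) correction: deep amplitude modulation can make the difference
function dip at a composite envelope–carrier period; any lag `tau/k`
(k = 2..5) whose normalized difference stays below 0.5 is preferred. Frames
whose best dip exceeds 0.35 are unvoiced; a clip with no voiced frame is an
error rather than a number.

**Stimulus normalization** trims clips to 750 ms, applies 100 ms
quarter-sine onset/offset ramps, and equalizes RMS.

## EEG preprocessing

The continuous recording (500 Hz, 13-channel scalp montage referenced to
Fpz) is re-referenced to the common average, filtered where a stage requires
it (ERPs: 0.1–30 Hz first-order Butterworth; a 4–8 Hz fourth-order zero-phase
variant is available for theta-filtered ERPs — forward–backward filtering
doubles the effective order, which is documented rather than hidden), and
epoched from −1 to 2 s around stimulus onsets (−2 to 3 s for time–frequency
work, wide enough that the 0–2 s analysis windows are never edge-
contaminated). Epochs are labeled by the sleep stage of the 20-s hypnogram
epoch containing onset — half-open intervals `[k·20, (k+1)·20)`, 0-based
sample indexing throughout — with N2/N3 pooled as NREM, N1 rejected as
unanalyzable transitional sleep, and unscored onsets rejected explicitly.
Visual artifact screening is replaced by reproducible amplitude (±300 µV)
and flatness (1 µV peak-to-peak) thresholds; every rejection records its
reason, and kept plus rejected always equals the number of events.
Participants with too few kept trials (default threshold 100; scaled runs
set it proportionally) are excluded from second-order statistics.

## Time–frequency decomposition

Morlet wavelets on a 1–30 Hz grid in 1 Hz steps are parameterized directly
by the FWHM of their Gaussian envelope, decreasing linearly from 1 s at 1 Hz
to 0.33 s at 30 Hz (1 cycle at 1 Hz, ~10 cycles at 30 Hz). Kernels are
truncated at 4σ and normalized to unit energy; since every downstream
quantity is baseline-corrected dB, ITPC, or a dB slope, the normalization
choice cannot leak into results. Convolution runs on the *continuous*
signal (centered kernels, so no phase lag), and only then are coefficients
epoched and decimated by 10 (to 50 Hz) — the wavelet itself band-limits the
coefficients, so decimation needs no extra anti-alias filter, and
decimation commutes with the linear band averaging.

Power is `10·ln(|z|²)` — the natural-logarithm dB convention, kept as the
default deliberately; a `db_log10` switch provides conventional
`10·log10`, which rescales every dB quantity by `ln 10` and nothing else.
Power is baselined per trial, channel and frequency against −0.5–0 s. ITPC
is the resultant length of unit phasors across trials per channel,
frequency and time — a first-order statistic computed within participant
and condition — then baselined per channel and frequency against −1–0 s
(per channel *before* channel averaging). Band averages are unweighted
means over inclusive integer bins: delta 1–4, theta 4–8, sigma 12–15 Hz.

## Statistics

First-order statistics average trials within participant × condition ×
state, compute ITPC across trials, or regress single-trial power on
z-scored stimulus features (z-scored over the 16-stimulus set, sample SD);
channels are averaged only after the per-channel computation. Roughness and
pitch are fitted in separate simple regressions by default — the stimulus
set is constructed pitch-matched, making the features nearly orthogonal —
with a joint-OLS option for correlated feature sets.

Second-order inference is a paired cluster-based permutation test on
participant × time series: two-tailed point-wise paired t-tests at
α = 0.05, contiguous same-signed supra-threshold runs scored by their
summed t values, and a null distribution of the maximum absolute cluster
score over random per-participant sign flips (5000 draws by default;
exhaustive enumeration for small n). The max-|statistic| null corrects over
both tails at once — the conservative standard choice when both positive
and negative clusters are reported. The Monte Carlo p-value carries the +1
correction so it is never exactly zero; non-significant clusters are
reported with their p rather than suppressed. Analysis windows are fixed a
priori: 0–2 s for power and power-regression series (induced activity is
long-lived), 0–1 s for ERP and ITPC series (evoked activity is short).
Effect sizes are Cohen's d = µ/s over participant-level cluster-extent
averages.

## The synthetic study generator

The generator exists so the pipeline can be validated against ground truth.
A session is built as:

* **background**: per-channel 1/f^β noise (β = 1, 15 µV SD) whose Welch
  slope is itself a tested invariant;
* **spontaneous sleep oscillations** in N2/N3: discrete slow waves (75 µV
  in N3, half in N2; 8/min and 3/min) and spindles (12–15 Hz, 15 µV, 3/min
  in N2, 1.5/min in N3) — densities are literature-plausible defaults, not
  estimates from any particular sample;
* **injected responses** per stimulus, by stage: a wake N1-P2-N2 ERP
  kernel; an NREM evoked slow wave (P200-N550-P900); a phase-locked 6 Hz
  theta burst whose von Mises phase concentration is
  `kappa = exp(ln kappa0 + g_theta · z_roughness)`; and a non-phase-locked
  13.5 Hz sigma burst in a 0.6–1.4 s Tukey window whose amplitude is linear
  in z-scored roughness on the dB scale — exactly the model the regression
  stage estimates. Ground-truth roughness is measured from the rendered
  audio with the package's own estimator, closing the loop between
  acoustics and EEG effects.

Three design points deserve emphasis because they were forced by the
physics of the measurement chain:

* **Topographies.** Components carry scalp gradients (anterior maximum for
  sleep oscillations and NREM responses, vertex maximum for ERP/theta). A
  common-average reference removes whatever is shared across channels; a
  topography-free synthetic response would be annihilated by
  re-referencing, which no real scalp field is.
* **A stationary sigma floor.** Log power of a near-silent background is
  scale-free noise (the log of a low-dof chi-square), so per-trial dB
  baselining of an unrealistically silent spindle band would be dominated
  by baseline noise at any trial count. A constant-amplitude, random-phase
  multi-sine background (10 µV across 12–15 Hz per channel) keeps baseline
  power finite and stable, as real EEG is. Unlike real sigma activity it
  does not wax and wane; the discrete spontaneous spindles carry that.
* **Effect-size defaults.** Where the emulated study fixes a condition
  (500 Hz, 13 channels, 5–11 s jitter, 22-stimulus blocks, 20-s hypnogram
  epochs, 8+8 pitch-matched stimuli), the defaults encode it. Effect
  gains have no stated values anywhere, so the defaults
  (`theta_kappa_per_roughness = 0.8`, `sigma_gain_db_per_sd = 1`,
  40 µV sigma burst, 12 µV theta burst) were calibrated once, at design
  time, so that the package's validation studies — 10 participants with 96
  NREM trials on a 4-channel gradient-spanning montage — detect the two
  target contrasts with clear margins. The weaker, literature-scale sigma
  slope of 0.2 dB per SD is exercised separately in the parameter-recovery
  analysis, which measures estimator bias rather than detection power.

What the generator does *not* emulate: volume-conduction mixing beyond
fixed gain maps, ocular and muscle artifacts beyond injected amplitude
transients, inter-participant heterogeneity of effect sizes (participants
differ only by noise), REM physiology, and the waxing–waning fine structure
of real spindles. Passing tests therefore demonstrate the correctness and
calibration of the estimators and inference — not that effects of this size
are detectable in real recordings at these trial counts.

## Validation scale and numerical choices

Simulation-based checks run at a deliberately reduced scale chosen as the
package's validation conditions: sessions at 250 Hz with decimation by 5
(preserving the identical 50 Hz decomposition grid of the 500 Hz /
factor-10 default), 4–6 channels spanning the montage gradient, 32–200
trials per session, and permutation counts of 1000 where 5000 is the
analysis default. Parameter recovery uses a low-background configuration
(2 µV noise, spontaneous oscillations and the sigma floor off, regression
on unbaselined dB power — the slope is invariant in expectation to the
per-trial baseline, which only adds variance). Degenerate inputs error
loudly rather than silently: zero-variance differences, constant features,
unvoiced clips, windows outside epochs, frame rates too low for the
roughness band, and sessions exceeding a configured duration cap.

## Known limitations

* The roughness scale depends on the MPS normalization; printed
  arbitrary-unit values from other implementations are comparable only up
  to that choice. Orderings and differences are the robust quantities.
* Clustering is over time only; channels are averaged beforehand, so no
  spatial inference is offered (no channel-adjacency clustering or TFCE).
* The EDF writer targets continuous 16-bit EDF with one record per second
  and integer microvolt ranges; it is meant for round-tripping synthetic
  sessions, not as a general-purpose clinical EDF library.
* Artifact screening is a reproducible surrogate (amplitude/flatness
  thresholds) for visual inspection and micro-arousal exclusion; thresholds
  are configuration, and results should be reported together with them.
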