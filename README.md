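# vocalsleep

EEG responses to rough (screamed) versus neutral vocalizations across
wakefulness and NREM sleep, as a tested, reusable analysis pipeline.

Screams differ from neutral vocalizations mainly in **roughness** — energy
in fast (30–150 Hz) amplitude modulations — and the question this pipeline
serves is whether the sleeping brain still privileges rough sounds.
`vocalsleep` is aimed at sleep/auditory EEG researchers who need the full
measurement chain:

* **Acoustics** — roughness from the modulation power spectrum (2-D Fourier
  transform of a short-window spectrogram; roughness = log₁₀ mean
  normalized modulation power over 30–150 Hz), fundamental frequency by a
  YIN-style difference function (40–1500 Hz), duration/ramp/RMS stimulus
  normalization.
* **Preprocessing** — Butterworth filtering, common-average referencing,
  epoching (−1 to 2 s), sleep-stage labeling from 20-s hypnogram epochs
  (N2/N3 → NREM, N1 and unscored rejected with reasons), amplitude/flatness
  artifact screening, baseline correction.
* **Time–frequency** — Morlet wavelets on a 1–30 Hz grid with envelope FWHM
  decreasing linearly from 1 s to 0.33 s, convolution on the continuous
  signal, decimation to 50 Hz, power in `10·ln(|z|²)` dB with −0.5–0 s
  baseline, and inter-trial phase coherence
  `ITPC = |Σₖ e^{iφₖ}| / N` with −1–0 s baseline; canonical band averages
  (delta 1–4, theta 4–8, sigma 12–15 Hz).
* **Statistics** — first-order trial averages and single-trial OLS
  regression of power on z-scored roughness/pitch; second-order paired
  cluster-based permutation tests (point-wise two-tailed t at α = 0.05,
  sum-of-t cluster scores, max-|cluster| sign-flip null, 5000 permutations,
  +1-corrected p), Cohen's d = µ/s.
* **Synthetic studies** — a polysomnography + stimulus generator with known
  ground truth (1/f background, spontaneous slow waves and spindles,
  topographic evoked responses, von Mises phase locking and dB-linear
  roughness effects) so every stage is testable without recorded data, plus
  WAV/EDF/TSV I/O for round-tripping sessions to disk.

## Worked example

Generate a pitch-matched scream/neutral stimulus set, simulate a small
NREM study, and test the two headline contrasts:

```r
library(vocalsleep)

st <- generate_stimulus_set(8, seed = 1)
head(st$features, 4)
#>   stimulus_id condition roughness pitch
#> 1    scream01    scream     -6.07   434
#> 2   neutral01   neutral     -7.27   434
#> 3    scream02    scream     -5.66   691
#> 4   neutral02   neutral     -6.94   691

cfg <- analysis_config(
  session = session_config(n_participants = 6, sampling_rate = 250,
                           channels = c("Fpz", "F3", "Cz", "P3"),
                           n_trials_wake = 0, n_trials_nrem = 72, seed = 42),
  bands = "sigma", states = "NREM", include_erp = FALSE,
  n_perm = 1000, min_kept_trials = 20, seed = 42)
b <- run_analysis(cfg)

b$results[["NREM.itpc_theta.scream_vs_neutral"]]
#> <cluster_test> n = 6 participants, 51 time points, 1000 permutations
#>   cluster 0.000-0.840 s: t_cluster = 198.36, p_cluster = 0.02398, mean 0.0718 +/- 0.0362, d = 1.98

b$results[["NREM.power_sigma.scream_vs_neutral"]]
#> <cluster_test> n = 6 participants, 101 time points, 1000 permutations
#>   cluster 0.700-1.280 s: t_cluster = 102.77, p_cluster = 0.04595, mean 1 +/- 0.716, d = 1.40

b$results[["NREM.beta_roughness.sigma"]]
#> <cluster_test> n = 6 participants, 101 time points, 1000 permutations
#>   cluster 0.660-1.340 s: t_cluster = 142.31, p_cluster = 0.03596, mean 0.603 +/- 0.367, d = 1.64
```

Reading the output: screams evoke more phase-consistent theta activity than
neutral vocalizations over 0–0.84 s (ITPC difference 0.072, Cohen's
d ≈ 2.0), more induced spindle-band power at the late 0.7–1.3 s latencies
typical of evoked sleep spindles (difference 1.0 dB in the natural-log dB
convention), and single-trial sigma power rises with stimulus roughness
(slope 0.60 dB per SD of roughness across that cluster) — the synthetic
study injected exactly these effects, which is how the pipeline is
validated. `report_json(b)` serializes all contrasts, QC and provenance;
`write_session()` / `read_edf()` round-trip sessions through EDF/TSV.

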