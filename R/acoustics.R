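## Acoustic characterization of vocal stimuli: spectrogram -> modulation power
## spectrum -> roughness (log relative modulation power, 30-150 Hz), plus a
## YIN-style fundamental-frequency estimator and the stimulus normalization
## (fixed duration, quarter-sine onset/offset ramps, RMS equalization).

#' Short-time Fourier magnitude spectrogram
#'
#' Thin wrapper around [signal::specgram()] with short analysis windows. The
#' defaults (10 ms Hann window, 1.25 ms hop at 16 kHz, i.e. an 800 Hz frame
#' rate) are chosen so that temporal envelope modulations up to at least
#' 150 Hz — the roughness range — are resolvable in the frame-to-frame
#' dynamics; classical 64 ms voice windows would low-pass the envelope far
#' below that.
#'
#' @param clip An [audio_clip()].
#' @param window_len Analysis window length in seconds.
#' @param hop Hop between successive frames in seconds.
#' @return A list of class `spectrogram`: `mag` (frequency x time magnitude
#'   matrix), `freqs` (Hz), `times` (s, frame centers), `frame_rate` (Hz),
#'   `rate` (audio rate, Hz).
#' @export
clip_spectrogram <- function(clip, window_len = 0.010, hop = 0.00125) {
  stopifnot(inherits(clip, "audio_clip"), hop > 0)
  n <- round(window_len * clip$rate)
  if (n < 2) stop("window_len too short: fewer than 2 samples per window")
  h <- max(1L, as.integer(round(hop * clip$rate)))
  if (length(clip$samples) < n)
    stop("clip shorter than one analysis window")
  sg <- signal::specgram(clip$samples, n = n, Fs = clip$rate,
                         window = signal::hanning(n), overlap = n - h)
  structure(list(mag = Mod(sg$S), freqs = as.numeric(sg$f),
                 times = as.numeric(sg$t), frame_rate = clip$rate / h,
                 rate = clip$rate),
            class = "spectrogram")
}

#' Modulation power spectrum of a spectrogram
#'
#' Applies a 2-D Fourier transform to the (log-compressed, mean-removed)
#' spectrogram, decomposing it into temporal modulation rates (Hz, from the
#' frame axis) and spectral modulations (cycles/Hz, from the frequency axis).
#' Log-amplitude compression makes the result invariant to overall gain: a
#' gain change adds a constant to the log spectrogram, which the mean removal
#' cancels. Power satisfies Parseval: its total equals the total squared
#' deviation of the compressed spectrogram.
#'
#' @param spec A `spectrogram` (see [clip_spectrogram()]).
#' @param log_compress Compress magnitudes as `log(mag + eps)` before the 2-D
#'   transform, with a 60 dB floor (`eps` = 1e-3 of the peak magnitude).
#'   Default `TRUE`.
#' @return A list of class `mps`: `power` (spectral-modulation x
#'   temporal-modulation), `rate_axis` (signed temporal modulation, Hz),
#'   `scale_axis` (signed spectral modulation, cycles/Hz), `frame_rate`.
#' @export
modulation_power_spectrum <- function(spec, log_compress = TRUE) {
  stopifnot(inherits(spec, "spectrogram"))
  m <- spec$mag
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("spectrogram must have at least 2 frequency rows and 2 frames")
  if (spec$frame_rate < 300)
    stop(sprintf(paste0("spectrogram frame rate (%.0f Hz) cannot resolve ",
                        "modulations up to 150 Hz; use a smaller hop"),
                 spec$frame_rate))
  peak <- max(m)
  ## 60 dB floor: magnitudes below 1e-3 of the peak are leakage/noise whose
  ## log-domain fluctuations would otherwise dominate the transform
  if (log_compress && peak > 0) m <- log(m + 1e-3 * peak)
  m <- m - mean(m)
  F2 <- stats::fft(m)
  power <- Mod(F2)^2 / length(m)
  nr <- nrow(m); nc <- ncol(m)
  rate_axis <- .fft_axis(nc, spec$frame_rate)
  df <- if (length(spec$freqs) > 1) diff(spec$freqs[1:2]) else 1
  scale_axis <- .fft_axis(nr, 1 / df)
  structure(list(power = power, rate_axis = rate_axis, scale_axis = scale_axis,
                 frame_rate = spec$frame_rate),
            class = "mps")
}

## signed DFT frequency axis for n bins at sampling rate fs
.fft_axis <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

#' Acoustic roughness from the modulation power spectrum
#'
#' Roughness is the base-10 log of the mean normalized modulation power over
#' temporal modulation rates in the 30-150 Hz band (both signs of the rate
#' axis pooled), i.e. the fraction of modulation energy carried by fast
#' amplitude modulations. Fast AM in this range is the defining acoustic
#' property of screamed vocalizations. The normalization (division by total
#' modulation power) makes the arbitrary-unit scale comparable across clips;
#' without it the measure would shift with overall modulation depth.
#'
#' @param mps An `mps` object (see [modulation_power_spectrum()]).
#' @param band Temporal modulation band in Hz, default `c(30, 150)`.
#' @return Roughness in log10 arbitrary units (scalar).
#' @export
roughness <- function(mps, band = c(30, 150)) {
  stopifnot(inherits(mps, "mps"), length(band) == 2L, band[1] < band[2])
  if (max(abs(mps$rate_axis)) < band[2])
    stop("modulation rate axis does not cover the requested band")
  sel <- abs(mps$rate_axis) >= band[1] & abs(mps$rate_axis) <= band[2]
  if (!any(sel)) stop("no modulation bins inside the band")
  total <- sum(mps$power)
  if (total <= 0) stop("zero modulation power (constant spectrogram)")
  log10(mean(mps$power[, sel]) / total)
}

#' Roughness of an audio clip
#'
#' Convenience composition `clip -> spectrogram -> MPS -> roughness` with the
#' package defaults.
#'
#' @param clip An [audio_clip()].
#' @return Roughness in log10 arbitrary units.
#' @export
clip_roughness <- function(clip) {
  roughness(modulation_power_spectrum(clip_spectrogram(clip)))
}

#' Fundamental frequency by the cumulative-mean-normalized difference function
#'
#' YIN-style estimator: per 50 ms frame, the difference function
#' `d(tau) = sum_j (x_j - x_{j+tau})^2` is normalized by its cumulative mean
#' and the first dip below `threshold` (with parabolic refinement) gives the
#' period. Frames whose best dip exceeds 0.35 are treated as unvoiced. The
#' clip-level estimate is the median over voiced frames. The search range
#' defaults to 40-1500 Hz, wide enough for high-pitched screamed
#' vocalizations (fundamentals approaching 1 kHz). Deep amplitude
#' modulation can make the difference function dip at a composite
#' envelope-carrier period rather than the carrier period; a sub-multiple
#' check therefore promotes any lag `tau/k` (k = 2..5) whose normalized
#' difference stays below 0.5, recovering the carrier fundamental.
#'
#' @param clip An [audio_clip()].
#' @param fmin,fmax Search range in Hz; `fmin < fmax < rate/2`.
#' @param threshold Dip threshold on the normalized difference function.
#' @return Estimated fundamental frequency in Hz.
#' @export
estimate_f0 <- function(clip, fmin = 40, fmax = 1500, threshold = 0.2) {
  stopifnot(inherits(clip, "audio_clip"))
  rate <- clip$rate
  if (!(fmin < fmax && fmax < rate / 2))
    stop("need fmin < fmax < Nyquist")
  tau_min <- max(2L, floor(rate / fmax))
  tau_max <- ceiling(rate / fmin)
  w <- tau_max                       # integration window (samples)
  frame_len <- 2L * tau_max
  hop <- max(1L, round(0.010 * rate))
  x <- clip$samples
  if (length(x) < frame_len) stop("clip too short for the requested fmin")
  starts <- seq(1L, length(x) - frame_len + 1L, by = hop)
  f0s <- rep(NA_real_, length(starts))
  taus <- tau_min:tau_max
  for (k in seq_along(starts)) {
    fr <- x[starts[k]:(starts[k] + frame_len - 1L)]
    if (all(fr == 0)) next
    d <- vapply(seq_len(tau_max), function(tau)
      sum((fr[1:w] - fr[(1 + tau):(w + tau)])^2), 0.0)
    dn <- d * seq_len(tau_max) / pmax(cumsum(d), .Machine$double.eps)
    dn_band <- dn[taus]
    below <- which(dn_band < threshold)
    i <- if (length(below)) {
      j <- below[1]
      while (j < length(dn_band) && dn_band[j + 1] < dn_band[j]) j <- j + 1L
      j
    } else which.min(dn_band)
    if (dn_band[i] > 0.35) next                      # unvoiced frame
    tau <- taus[i]
    for (div in 5:2) {                               # octave-error correction
      tau_k <- as.integer(round(tau / div))
      if (tau_k >= tau_min && dn[tau_k] < 0.5) {
        tau <- tau_k
        break
      }
    }
    if (tau > tau_min && tau < tau_max) {            # parabolic refinement
      y0 <- dn[tau - 1L]; y1 <- dn[tau]; y2 <- dn[tau + 1L]
      den <- y0 - 2 * y1 + y2
      if (abs(den) > .Machine$double.eps)
        tau <- tau + 0.5 * (y0 - y2) / den
    }
    f0s[k] <- rate / tau
  }
  voiced <- f0s[!is.na(f0s)]
  if (!length(voiced)) stop("no voiced frame detected")
  median(voiced)
}

#' Normalize a clip's duration, onsets and intensity
#'
#' Trims the clip to exactly `target_duration`, applies quarter-sine onset and
#' offset ramps of `ramp` seconds (`env(t) = sin(pi/2 * t / ramp)` for
#' `t < ramp`, mirrored at the offset), and rescales to `target_rms`.
#'
#' @param clip An [audio_clip()].
#' @param target_duration Output duration in seconds; must exceed `2 * ramp`.
#' @param ramp Ramp length in seconds.
#' @param target_rms Target root-mean-square amplitude.
#' @return A normalized [audio_clip()] of exactly
#'   `round(target_duration * rate)` samples.
#' @export
normalize_clip <- function(clip, target_duration = 0.75, ramp = 0.1,
                           target_rms = 0.05) {
  stopifnot(inherits(clip, "audio_clip"), target_duration > 2 * ramp,
            target_rms > 0)
  n_out <- round(target_duration * clip$rate)
  if (length(clip$samples) < n_out)
    stop("clip shorter than the target duration")
  x <- clip$samples[seq_len(n_out)]
  nr <- round(ramp * clip$rate)
  if (nr > 0) {
    i <- 0:(nr - 1)
    env <- sin(pi / 2 * i / nr)
    x[1:nr] <- x[1:nr] * env
    x[(n_out - nr + 1):n_out] <- x[(n_out - nr + 1):n_out] * rev(env)
  }
  rms <- sqrt(mean(x^2))
  if (rms <= 0) stop("cannot RMS-normalize a silent clip")
  audio_clip(x * target_rms / rms, clip$rate)
}

#' Extract per-stimulus acoustic features
#'
#' Computes roughness and fundamental frequency for each clip of a stimulus
#' set (or any named list of clips) and returns the feature table consumed by
#' the regression analyses.
#'
#' @param clips Named list of [audio_clip()] objects, or a `stimulus_set`.
#' @param conditions Optional character vector of condition labels, recycled
#'   against `clips`.
#' @param path Optional TSV output path.
#' @return Data frame with columns `stimulus_id`, `condition`, `roughness`,
#'   `f0`.
#' @export
stimulus_features <- function(clips, conditions = NA_character_, path = NULL) {
  if (inherits(clips, "stimulus_set")) {
    conditions <- vapply(clips$specs, function(s) s$condition, "")
    clips <- clips$clips
  }
  stopifnot(is.list(clips), length(clips) > 0L)
  ids <- names(clips)
  if (is.null(ids)) ids <- sprintf("stim%02d", seq_along(clips))
  feats <- data.frame(
    stimulus_id = ids,
    condition = rep_len(conditions, length(clips)),
    roughness = vapply(clips, clip_roughness, 0.0),
    f0 = vapply(clips, estimate_f0, 0.0),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path))
    write.table(feats, path, sep = "\t", row.names = FALSE, quote = FALSE)
  feats
}
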