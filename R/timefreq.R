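## Morlet wavelet time-frequency decomposition. Wavelets are complex
## exponentials under a Gaussian envelope parameterized directly by the
## envelope's full width at half maximum (FWHM), decreasing linearly from
## 1 s at 1 Hz to 0.33 s at 30 Hz (1 cycle at 1 Hz, ~10 cycles at 30 Hz).
## Convolution runs on the continuous signal (FFT overlap-free, centered
## kernels, so symmetric wavelets introduce no phase lag); epoching and
## 10x downsampling happen afterwards.

.band_bins <- list(delta = 1:4, theta = 4:8, sigma = 12:15)

#' FWHM schedule of the wavelet bank
#'
#' Linear interpolation from 1 s at 1 Hz down to 0.33 s at 30 Hz:
#' `fwhm(f) = 1 - (f - 1) * (1 - 0.33) / 29`.
#'
#' @param freqs Frequencies in Hz.
#' @return FWHM in seconds, same length as `freqs`.
#' @export
wavelet_fwhm <- function(freqs) 1 - (freqs - 1) * (1 - 0.33) / 29

#' Build a Morlet wavelet bank
#'
#' Each kernel is `exp(2i*pi*f*t) * exp(-t^2 / (2*sigma^2))` with
#' `sigma = fwhm / (2*sqrt(2*log(2)))`, truncated at 4 sigma and normalized
#' to unit energy. Unit-energy normalization makes absolute power depend on
#' the kernel, but every quantity used downstream (baseline-corrected dB,
#' ITPC, regression slopes on dB) is invariant to it.
#'
#' @param rate Sampling rate of the signal to be decomposed, Hz (>= 60).
#' @param freqs Frequency grid in Hz; the full analysis grid is `1:30`
#'   (1-Hz steps). A subset (e.g. only the bands an analysis needs) is
#'   allowed and cheaper.
#' @return An object of class `wavelet_bank`: `freqs`, `fwhm` (s),
#'   `kernels` (list of complex vectors, odd lengths), `half` (half-lengths
#'   in samples), `rate`.
#' @export
build_wavelet_bank <- function(rate, freqs = 1:30) {
  stopifnot(rate >= 2 * max(freqs), all(freqs > 0))
  fwhm <- wavelet_fwhm(freqs)
  kernels <- vector("list", length(freqs))
  half <- integer(length(freqs))
  for (i in seq_along(freqs)) {
    sigma <- fwhm[i] / (2 * sqrt(2 * log(2)))
    h <- ceiling(4 * sigma * rate)
    t <- (-h:h) / rate
    k <- exp(2i * pi * freqs[i] * t) * exp(-t^2 / (2 * sigma^2))
    kernels[[i]] <- k / sqrt(sum(Mod(k)^2))
    half[i] <- h
  }
  structure(list(freqs = freqs, fwhm = fwhm, kernels = kernels, half = half,
                 rate = rate),
            class = "wavelet_bank")
}

#' Time-frequency transform of continuous EEG around events
#'
#' Convolves every channel of the continuous recording with every wavelet of
#' the bank (FFT convolution, centered), then epochs the complex
#' coefficients around the event onsets and keeps every `downsample`-th
#' sample — the wavelet itself band-limits the coefficients, so plain
#' decimation needs no extra anti-alias filter. Events whose epoch plus the
#' widest kernel's support would leave the recording are flagged
#' (`valid = FALSE`); their coefficients are edge-contaminated.
#'
#' @param eeg An [eeg_continuous()].
#' @param bank A [build_wavelet_bank()] result with `bank$rate == eeg$rate`.
#' @param events Event data frame with 0-based `onset_sample`.
#' @param window Epoch window in seconds, default `c(-2, 3)` (wider than the
#'   analysis windows so they are never edge-contaminated).
#' @param downsample Decimation factor after convolution, default 10.
#' @return An object of class `tfr_complex`: `values` (complex array trials
#'   x channels x freqs x time), `times` (s), `freqs` (Hz), `rate`
#'   (effective, Hz), `valid` (logical per trial), `info` (the event rows).
#' @export
tfr_transform <- function(eeg, bank, events, window = c(-2, 3),
                          downsample = 10) {
  stopifnot(inherits(eeg, "eeg_continuous"), inherits(bank, "wavelet_bank"),
            bank$rate == eeg$rate, window[1] < 0, window[2] > 0)
  rate <- eeg$rate
  n <- ncol(eeg$data)
  off <- seq(round(window[1] * rate), round(window[2] * rate), by = downsample)
  times <- off / rate
  n_ev <- nrow(events)
  n_ch <- nrow(eeg$data)
  n_f <- length(bank$freqs)
  half_max <- max(bank$half)

  nfft <- stats::nextn(n + 2L * half_max + 1L, 2)
  K <- vector("list", n_f)
  for (j in seq_len(n_f)) {
    kw <- complex(real = numeric(nfft))
    kw[seq_along(bank$kernels[[j]])] <- bank$kernels[[j]]
    K[[j]] <- stats::fft(kw)
  }

  vals <- array(NA_complex_, c(n_ev, n_ch, n_f, length(times)))
  onset1 <- events$onset_sample + 1L                     # 1-based center
  valid <- (onset1 + off[1] - half_max >= 1L) &
           (onset1 + off[length(off)] + half_max <= n)
  in_range <- (onset1 + off[1] >= 1L) & (onset1 + off[length(off)] <= n)
  for (c_i in seq_len(n_ch)) {
    xw <- complex(real = numeric(nfft))
    xw[seq_len(n)] <- eeg$data[c_i, ]
    X <- stats::fft(xw)
    for (j in seq_len(n_f)) {
      y <- stats::fft(X * K[[j]], inverse = TRUE) / nfft
      c0 <- bank$half[j] + 1L                            # kernel center index
      for (k in seq_len(n_ev)) {
        if (!in_range[k]) next
        vals[k, c_i, j, ] <- y[onset1[k] + off + c0 - 1L]
      }
    }
  }
  structure(list(values = vals, times = times, freqs = bank$freqs,
                 rate = rate / downsample, valid = valid & in_range,
                 info = events),
            class = "tfr_complex")
}

#' Power in decibels from complex coefficients
#'
#' Squares the modulus and maps to decibels. The default follows the
#' convention `10 * ln(|z|^2)` (natural logarithm); `db_log10 = TRUE`
#' switches to the conventional `10 * log10(|z|^2)`, which only rescales all
#' values by `ln(10)`. Zero moduli are floored at the smallest positive
#' double before the logarithm.
#'
#' @param tfr A `tfr_complex`.
#' @param db_log10 Use base-10 logarithm instead of the natural logarithm.
#' @return An object of class `tfr_power` with the same shape and axes.
#' @export
power_db <- function(tfr, db_log10 = FALSE) {
  stopifnot(inherits(tfr, "tfr_complex"))
  p <- pmax(Mod(tfr$values)^2, .Machine$double.xmin)
  v <- if (db_log10) 10 * log10(p) else 10 * log(p)
  structure(list(values = array(v, dim(tfr$values)), times = tfr$times,
                 freqs = tfr$freqs, rate = tfr$rate, valid = tfr$valid,
                 info = tfr$info, db_log10 = db_log10,
                 baseline = NULL),
            class = "tfr_power")
}

#' Baseline-correct time-frequency power
#'
#' Subtracts, per trial, channel and frequency, the mean power over a
#' pre-stimulus window (default -0.5 to 0 s).
#'
#' @param p A `tfr_power`.
#' @param window Baseline window in seconds.
#' @return The corrected `tfr_power` (its `baseline` field records the
#'   window).
#' @export
baseline_power <- function(p, window = c(-0.5, 0)) {
  stopifnot(inherits(p, "tfr_power"), window[1] < window[2])
  sel <- p$times >= window[1] & p$times <= window[2]
  if (!any(sel)) stop("baseline window outside the epoch")
  bl <- apply(p$values[, , , sel, drop = FALSE], 1:3, mean)
  p$values <- p$values - array(bl, dim(p$values))
  p$baseline <- window
  p
}

#' Inter-trial phase coherence
#'
#' For every channel, frequency and time point, the resultant length of the
#' unit phasors of the per-trial phases:
#' `ITPC = |sum_k exp(i*phi_k)| / N`. The raw value lies in \[0, 1\]
#' (1 = perfect phase locking; expectation `sqrt(pi/(4N))` under uniform
#' phases) and is by construction invariant to per-trial amplitude. A
#' baseline correction then subtracts, per channel and frequency, the mean
#' ITPC over the pre-stimulus window (default -1 to 0 s), giving values in
#' \[-1, 1\]. ITPC is a first-order statistic: it is computed across the
#' trials of one participant and condition.
#'
#' @param tfr A `tfr_complex` (only `valid` trials should be passed; use
#'   [subset_trials()]).
#' @param baseline Baseline window in seconds, or `NULL` to skip.
#' @return An object of class `itpc_map`: `values` (baseline-corrected
#'   channels x freqs x time), `raw` (uncorrected), `n_trials`, `times`,
#'   `freqs`, `baseline`.
#' @export
itpc <- function(tfr, baseline = c(-1, 0)) {
  stopifnot(inherits(tfr, "tfr_complex"))
  n_tr <- dim(tfr$values)[1]
  if (n_tr < 2) stop("ITPC requires at least 2 trials")
  m <- Mod(tfr$values)
  u <- tfr$values / ifelse(m > 0, m, 1)
  um <- matrix(u, nrow = n_tr)
  raw <- array(Mod(colMeans(um)), dim(tfr$values)[2:4])
  vals <- raw
  if (!is.null(baseline)) {
    sel <- tfr$times >= baseline[1] & tfr$times <= baseline[2]
    if (!any(sel)) stop("ITPC baseline window outside the epoch")
    bl <- apply(raw[, , sel, drop = FALSE], 1:2, mean)
    vals <- raw - array(bl, dim(raw))
  }
  structure(list(values = vals, raw = raw, n_trials = n_tr,
                 times = tfr$times, freqs = tfr$freqs, baseline = baseline),
            class = "itpc_map")
}

#' Keep a subset of trials of a time-frequency object
#'
#' @param x A `tfr_complex` or `tfr_power`.
#' @param keep Logical or integer index over trials.
#' @return The subset object.
#' @export
subset_trials <- function(x, keep) {
  stopifnot(inherits(x, c("tfr_complex", "tfr_power")))
  x$values <- x$values[keep, , , , drop = FALSE]
  x$valid <- x$valid[keep]
  x$info <- x$info[keep, , drop = FALSE]
  x
}

#' Average over a canonical frequency band
#'
#' Unweighted mean over the band's inclusive integer bins on the 1-Hz grid:
#' delta = 1-4 Hz (bins 1,2,3,4), theta = 4-8 Hz (bins 4..8), sigma =
#' 12-15 Hz (bins 12..15) — the canonical bands of sleep EEG research.
#'
#' @param x A `tfr_power` (trials x channels x freqs x time) or `itpc_map`
#'   (channels x freqs x time).
#' @param band `"delta"`, `"theta"` or `"sigma"`.
#' @return The same object minus the frequency dimension: trials x channels
#'   x time (power) or channels x time (ITPC), with a `band` attribute.
#' @export
band_average <- function(x, band) {
  if (!band %in% names(.band_bins)) stop("unknown band: ", band)
  bins <- .band_bins[[band]]
  if (!all(bins %in% x$freqs))
    stop(sprintf("band '%s' needs frequency bins %s on the grid", band,
                 paste(bins, collapse = ",")))
  j <- match(bins, x$freqs)
  if (inherits(x, "tfr_power")) {
    out <- apply(x$values[, , j, , drop = FALSE], c(1, 2, 4), mean)
  } else if (inherits(x, "itpc_map")) {
    out <- apply(x$values[, j, , drop = FALSE], c(1, 3), mean)
  } else stop("band_average expects a tfr_power or itpc_map")
  attr(out, "band") <- band
  attr(out, "times") <- x$times
  out
}
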