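## Preprocessing of continuous polysomnographic EEG: filtering,
## re-referencing, epoching around stimulus onsets, vigilance-state labeling
## from the hypnogram, automatic artifact screening, baseline correction.
## Trials are never dropped: every operation keeps one row of bookkeeping per
## event with a kept flag and a rejection reason, so kept + rejected always
## equals the number of events.

#' Continuous EEG container
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param rate Sampling rate, Hz.
#' @param channels Character vector of unique channel labels.
#' @param reference Reference description, e.g. `"Fpz"` (online) or
#'   `"common-average"`.
#' @return An object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, rate, channels = rownames(data),
                           reference = "Fpz") {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nrow(data)))
  stopifnot(rate > 0, length(channels) == nrow(data),
            !anyDuplicated(channels))
  rownames(data) <- channels
  structure(list(data = data, rate = rate, channels = channels,
                 reference = reference),
            class = "eeg_continuous")
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat(sprintf("<eeg_continuous> %d channels x %d samples @ %g Hz (%.1f min), ref %s\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate / 60,
              x$reference))
  invisible(x)
}

#' Butterworth bandpass filtering
#'
#' Filters every channel with a Butterworth bandpass of the stated order.
#' With `zero_phase = TRUE` the filter is applied forward and backward
#' (`signal::filtfilt`), which cancels group delay but doubles the effective
#' order (an order-4 zero-phase filter has an order-8 magnitude response).
#'
#' @param eeg An [eeg_continuous()].
#' @param low,high Band edges in Hz, `0 < low < high < rate/2`.
#' @param order Filter order (>= 1).
#' @param zero_phase Apply forward-backward filtering. Default `FALSE`
#'   (single-pass causal filtering).
#' @return A filtered [eeg_continuous()].
#' @export
bandpass <- function(eeg, low, high, order = 1, zero_phase = FALSE) {
  stopifnot(inherits(eeg, "eeg_continuous"), order >= 1,
            low >= 0, low < high, high < eeg$rate / 2)
  bf <- signal::butter(order, c(low, high) / (eeg$rate / 2), type = "pass")
  if (any(!is.finite(unlist(bf))))
    stop("unstable filter design for this band/order/rate")
  out <- eeg
  for (i in seq_len(nrow(eeg$data))) {
    x <- eeg$data[i, ]
    out$data[i, ] <- if (zero_phase) signal::filtfilt(bf, x)
                     else as.numeric(signal::filter(bf, x))
  }
  out
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over the included (good) channels, so
#' that the mean of the good channels is zero everywhere afterwards. Bad
#' channels are excluded from the average but still re-referenced.
#'
#' @param eeg An [eeg_continuous()].
#' @param good Logical vector marking channels included in the average
#'   (default: all).
#' @return An [eeg_continuous()] with `reference = "common-average"`.
#' @export
rereference_common_average <- function(eeg, good = rep(TRUE, nrow(eeg$data))) {
  stopifnot(inherits(eeg, "eeg_continuous"),
            length(good) == nrow(eeg$data))
  if (sum(good) < 2) stop("need at least 2 good channels for an average reference")
  avg <- colMeans(eeg$data[good, , drop = FALSE])
  out <- eeg
  out$data <- sweep(eeg$data, 2, avg, "-")
  out$reference <- "common-average"
  out
}

#' Epoch continuous EEG around stimulus onsets
#'
#' Cuts one trial per event row. The window `[lo, hi]` (seconds relative to
#' onset) maps to `round((hi - lo) * rate) + 1` samples with the onset at
#' sample index `round(-lo * rate)` (0-based). Events whose window falls
#' outside the recording are flagged `kept = FALSE, reason = "edge"` and
#' their data left `NA`; they are not dropped.
#'
#' @param eeg An [eeg_continuous()].
#' @param events Event data frame with 0-based `onset_sample` plus stimulus
#'   feature columns (`stimulus_id`, `condition`, `roughness`, `pitch`).
#' @param window Length-2 numeric, seconds relative to onset; must contain 0.
#' @return An object of class `epoch_set`: `data` (trials x channels x time
#'   array), `times` (s), `rate`, `channels`, and `info` (one row per event:
#'   features plus `vigilance`, `kept`, `reason`).
#' @export
epoch_eeg <- function(eeg, events, window = c(-1, 2)) {
  stopifnot(inherits(eeg, "eeg_continuous"), length(window) == 2L,
            window[1] < 0, window[2] > 0)
  rate <- eeg$rate
  n_t <- round(diff(window) * rate) + 1L
  i0 <- round(window[1] * rate)
  times <- (i0 + 0:(n_t - 1L)) / rate
  n_ev <- nrow(events)
  dat <- array(NA_real_, c(n_ev, nrow(eeg$data), n_t))
  kept <- rep(TRUE, n_ev); reason <- rep(NA_character_, n_ev)
  for (k in seq_len(n_ev)) {
    idx <- events$onset_sample[k] + i0 + 0:(n_t - 1L) + 1L   # to 1-based
    if (idx[1] < 1L || idx[n_t] > ncol(eeg$data)) {
      kept[k] <- FALSE; reason[k] <- "edge"
    } else {
      dat[k, , ] <- eeg$data[, idx]
    }
  }
  info <- events
  info$vigilance <- NA_character_
  info$kept <- kept
  info$reason <- reason
  structure(list(data = dat, times = times, rate = rate,
                 channels = eeg$channels, window = window, info = info),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%d kept) x %d channels x %d samples, window [%g, %g] s\n",
              dim(x$data)[1], sum(x$info$kept), dim(x$data)[2], dim(x$data)[3],
              x$window[1], x$window[2]))
  invisible(x)
}

#' Label epochs with the vigilance state at stimulus onset
#'
#' Each onset is assigned the sleep stage of the 20-s hypnogram epoch that
#' contains it; hypnogram epochs are half-open intervals
#' `[k*20, (k+1)*20)` seconds. `W` maps to `wake`, `N2`/`N3` to `NREM`, `R`
#' to `REM`. Onsets during `N1` are flagged rejected (`reason = "N1"`,
#' transitional sleep is not analyzable as either state); onsets beyond the
#' hypnogram are flagged `reason = "unscored"`.
#'
#' @param epochs An [epoch_eeg()] result.
#' @param hyp A [hypnogram()].
#' @return The `epoch_set` with `vigilance`, `kept`, `reason` updated.
#' @export
label_epochs <- function(epochs, hyp) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(hyp, "hypnogram"))
  onset_s <- epochs$info$onset_sample / epochs$rate
  ei <- floor(onset_s / hyp$epoch_length) + 1L     # 1-based epoch index
  info <- epochs$info
  for (k in seq_len(nrow(info))) {
    if (ei[k] < 1L || ei[k] > length(hyp$stages)) {
      info$kept[k] <- FALSE
      if (is.na(info$reason[k])) info$reason[k] <- "unscored"
      next
    }
    st <- hyp$stages[ei[k]]
    info$vigilance[k] <- switch(st, W = "wake", N2 = "NREM", N3 = "NREM",
                                R = "REM", N1 = NA_character_)
    if (st == "N1" && info$kept[k]) {
      info$kept[k] <- FALSE; info$reason[k] <- "N1"
    }
  }
  epochs$info <- info
  epochs
}

#' Automatic artifact screening
#'
#' Surrogate for visual artifact and micro-arousal rejection: a trial is
#' rejected if any channel exceeds `abs_threshold` microvolts in absolute
#' value (`reason = "amplitude"`) or if every channel's peak-to-peak range is
#' below `flat_threshold` microvolts (`reason = "flat"`, dead signal).
#' Already-rejected trials are left untouched. A participant-level QC flag
#' (`attr(, "qc")`) records whether fewer than `min_kept` trials survive —
#' the exclusion rule applied to participants with too few unartefacted
#' trials.
#'
#' @param epochs An `epoch_set`.
#' @param abs_threshold Absolute amplitude threshold, microvolts (> 0).
#' @param flat_threshold Peak-to-peak flatness threshold, microvolts (> 0).
#' @param min_kept Minimum kept-trial count before the participant is flagged
#'   (the emulated study used 100).
#' @return The `epoch_set` with rejection flags and a `qc` attribute
#'   (list: `n_kept`, `n_rejected_by_reason`, `flag_low_trials`).
#' @export
reject_artifacts <- function(epochs, abs_threshold = 300, flat_threshold = 1,
                             min_kept = 100) {
  stopifnot(inherits(epochs, "epoch_set"), abs_threshold > 0,
            flat_threshold > 0)
  info <- epochs$info
  n_ch <- dim(epochs$data)[2]
  for (k in seq_len(nrow(info))) {
    if (!info$kept[k]) next
    tr <- matrix(epochs$data[k, , ], nrow = n_ch)
    if (max(abs(tr)) > abs_threshold) {
      info$kept[k] <- FALSE; info$reason[k] <- "amplitude"
    } else if (max(apply(tr, 1, function(z) diff(range(z)))) < flat_threshold) {
      info$kept[k] <- FALSE; info$reason[k] <- "flat"
    }
  }
  epochs$info <- info
  attr(epochs, "qc") <- list(
    n_kept = sum(info$kept),
    n_rejected_by_reason = table(info$reason[!info$kept]),
    flag_low_trials = sum(info$kept) < min_kept)
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over a pre-stimulus window.
#'
#' @param epochs An `epoch_set`.
#' @param window Length-2 numeric in seconds, inside the epoch and ending at
#'   or before 0 (default `c(-0.5, 0)`).
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-0.5, 0)) {
  stopifnot(inherits(epochs, "epoch_set"), window[1] < window[2],
            window[2] <= 0)
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) stop("baseline window outside the epoch")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(bl, dim(epochs$data))
  epochs
}

#' QC summary of an epoch set
#'
#' @param epochs An `epoch_set` (ideally after [label_epochs()] and
#'   [reject_artifacts()]).
#' @return A list: kept/rejected counts, counts per rejection reason and per
#'   vigilance state.
#' @export
qc_summary <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  info <- epochs$info
  list(n_events = nrow(info),
       n_kept = sum(info$kept),
       by_reason = table(info$reason[!info$kept], useNA = "no"),
       kept_by_state = table(info$vigilance[info$kept], useNA = "no"))
}
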