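## First-order statistics: quantities computed within a participant before
## across-participant inference — trial averages per condition, and
## single-trial regression slopes of oscillatory power on z-scored acoustic
## features. Channels are averaged after the per-channel computation.

#' Z-score a stimulus feature
#'
#' Centers and scales to unit sample SD (n-1 denominator).
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Standardized values (mean 0, SD 1).
#' @export
zscore_features <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  if (length(unique(values)) < 2) stop("constant feature cannot be z-scored")
  (values - mean(values)) / sd(values)
}

#' Trial averages per participant and condition
#'
#' Averages trials within participant x condition, then averages channels,
#' yielding one time series per participant and condition.
#'
#' @param values Numeric array, trials x channels x time.
#' @param participant Vector of participant ids, one per trial.
#' @param condition Vector of condition labels, one per trial.
#' @return A list of class `first_order`: `values` (array participants x
#'   conditions x time), `participants`, `conditions`, `n_trials` (matrix of
#'   trial counts), `empty_cells` (logical matrix; participants with an
#'   empty cell must be excluded from second-order statistics).
#' @export
first_order <- function(values, participant, condition) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(participant),
            length(participant) == length(condition))
  ps <- sort(unique(participant))
  cs <- sort(unique(condition))
  nt <- dim(values)[3]
  out <- array(NA_real_, c(length(ps), length(cs), nt),
               dimnames = list(ps, cs, NULL))
  counts <- matrix(0L, length(ps), length(cs), dimnames = list(ps, cs))
  for (i in seq_along(ps)) for (j in seq_along(cs)) {
    k <- which(participant == ps[i] & condition == cs[j])
    counts[i, j] <- length(k)
    if (length(k))
      out[i, j, ] <- apply(values[k, , , drop = FALSE], 3, mean)
  }
  structure(list(values = out, participants = ps, conditions = cs,
                 n_trials = counts, empty_cells = counts == 0L),
            class = "first_order")
}

#' Single-trial regression of power on a stimulus feature
#'
#' At every (channel, frequency, time) point — or any trailing shape —
#' regresses the per-trial values on a z-scored stimulus feature by ordinary
#' least squares and returns the slope. All stimuli (both conditions) enter
#' one regression. With `feature2` given and `joint = TRUE`, both features
#' enter a joint multiple regression and the slope for `feature` is
#' returned; the default is separate simple regressions, appropriate when
#' the features are close to orthogonal by stimulus design.
#'
#' @param power Numeric array whose first dimension is trials (e.g. trials x
#'   channels x freqs x time, or trials x channels x time).
#' @param feature Numeric per-trial regressor (z-score it first with
#'   [zscore_features()]).
#' @param feature2 Optional second regressor for a joint fit.
#' @param joint Fit both features jointly. Default `FALSE`.
#' @return Array of slopes with the shape of `power` minus the trial
#'   dimension.
#' @export
single_trial_regression <- function(power, feature, feature2 = NULL,
                                    joint = FALSE) {
  dm <- dim(power)
  if (is.null(dm)) dm <- c(length(power), 1L)
  n <- dm[1]
  stopifnot(length(feature) == n, n >= 3)
  if (var(feature) == 0) stop("feature has zero variance")
  m <- matrix(power, nrow = n)
  if (joint) {
    if (is.null(feature2)) stop("joint = TRUE requires feature2")
    X <- cbind(1, feature, feature2)
    XtX <- crossprod(X)
    if (abs(det(XtX)) < .Machine$double.eps) stop("singular design")
    B <- solve(XtX, crossprod(X, m))
    beta <- B[2, ]
  } else {
    zc <- feature - mean(feature)
    mc <- sweep(m, 2, colMeans(m))
    beta <- colSums(zc * mc) / sum(zc^2)
  }
  if (length(dm) > 2) array(beta, dm[-1]) else as.numeric(beta)
}
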