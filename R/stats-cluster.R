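## Second-order inference: paired cluster-based permutation tests on
## participant x time series. Point-wise two-tailed paired t-tests at
## alpha = 0.05 define clusters as contiguous supra-threshold runs of equal
## sign; each cluster is scored by the sum of its t values; the Monte Carlo
## null is the maximum absolute cluster score under random per-participant
## sign flips of the paired differences (max-statistic correction over both
## tails).

## contiguous supra-threshold runs of constant sign; returns a data frame
.find_clusters <- function(tvec, crit) {
  lab <- ifelse(abs(tvec) > crit, sign(tvec), 0)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep))
    return(data.frame(istart = integer(), iend = integer(),
                      stat = numeric(), sign = numeric()))
  data.frame(istart = starts[keep], iend = ends[keep],
             stat = vapply(which(keep),
                           function(i) sum(tvec[starts[i]:ends[i]]), 0.0),
             sign = r$values[keep])
}

.max_cluster_stat <- function(tvec, crit) {
  cl <- .find_clusters(tvec, crit)
  if (nrow(cl) == 0) 0 else max(abs(cl$stat))
}

#' Paired cluster-based permutation test on time series
#'
#' Tests a participants x time matrix `a` against `b` (or against zero) with
#' point-wise two-tailed paired t-tests; contiguous runs of time points with
#' `p < alpha_point` and a common sign form clusters scored by the sum of
#' their t values. Significance is assessed against the permutation
#' distribution of the maximum absolute cluster score obtained by randomly
#' flipping the sign of each participant's difference series (`n_perm` Monte
#' Carlo draws, or all `2^n` sign patterns when `exhaustive = TRUE`). The
#' Monte Carlo p-value uses the +1 correction,
#' `p = (1 + #(null >= |observed|)) / (1 + n_perm)`, so it is never exactly
#' zero; the exhaustive p is the exact proportion. For each cluster the
#' difference series is averaged over the cluster's time extent per
#' participant, and the mean, SD and Cohen's d of those values are reported.
#' Clusters with p >= 0.05 are reported too (with their p), not suppressed.
#'
#' @param a Numeric matrix, participants x time.
#' @param b Matrix like `a`, or `NULL` to test `a` against zero.
#' @param times Time axis in seconds (length `ncol(a)`).
#' @param window Optional analysis window `c(lo, hi)` in seconds; points
#'   outside are ignored (the emulated analyses use 0-2 s for power and
#'   regression series, 0-1 s for ERP and ITPC series).
#' @param alpha_point Point-wise two-tailed threshold, default 0.05.
#' @param n_perm Number of Monte Carlo permutations, default 5000.
#' @param seed Integer seed for the permutation draw (recorded in the
#'   result).
#' @param exhaustive Enumerate all `2^n` sign patterns instead of sampling
#'   (n <= 16).
#' @return An object of class `cluster_test`: `clusters` (data frame:
#'   `start_s`, `end_s`, `n_points`, `stat`, `p`, `sign`, `mean_diff`,
#'   `sd_diff`, `d`), `t` (observed t series), `times`, `n`, `n_perm`,
#'   `alpha_point`, `seed`, `exhaustive`.
#' @export
paired_cluster_permutation <- function(a, b = NULL, times = NULL,
                                       window = NULL, alpha_point = 0.05,
                                       n_perm = 5000, seed = NULL,
                                       exhaustive = FALSE) {
  a <- as.matrix(a)
  if (!is.null(b)) {
    b <- as.matrix(b)
    stopifnot(identical(dim(a), dim(b)))
  }
  n <- nrow(a)
  if (n < 2) stop("need at least 2 participants")
  if (is.null(times)) times <- seq_len(ncol(a))
  stopifnot(length(times) == ncol(a))
  sel <- if (is.null(window)) rep(TRUE, ncol(a))
         else times >= window[1] & times <= window[2]
  if (!any(sel)) stop("analysis window contains no time points")
  D <- (if (is.null(b)) a else a - b)[, sel, drop = FALSE]
  tsel <- times[sel]
  nt <- ncol(D)

  mu <- colMeans(D)
  s <- apply(D, 2, sd)
  if (all(s == 0)) stop("degenerate input: zero-variance differences everywhere")
  s[s == 0] <- .Machine$double.eps
  tobs <- mu / (s / sqrt(n))
  crit <- qt(1 - alpha_point / 2, df = n - 1)
  cl <- .find_clusters(tobs, crit)

  if (exhaustive) {
    if (n > 16) stop("exhaustive enumeration limited to n <= 16")
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_eff <- nrow(S)
  } else {
    if (!is.null(seed)) set.seed(seed)
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    n_eff <- n_perm
  }
  M <- S %*% D / n
  ssq <- colSums(D^2)                       # invariant under sign flips
  varm <- sweep(-n * M^2, 2, ssq, "+") / (n - 1)
  varm[varm < .Machine$double.eps] <- .Machine$double.eps
  Tm <- M / sqrt(varm / n)
  null_max <- vapply(seq_len(n_eff),
                     function(i) .max_cluster_stat(Tm[i, ], crit), 0.0)

  if (nrow(cl)) {
    cl$p <- vapply(cl$stat, function(st) {
      if (exhaustive) mean(null_max >= abs(st))
      else (1 + sum(null_max >= abs(st))) / (1 + n_perm)
    }, 0.0)
    summ <- t(vapply(seq_len(nrow(cl)), function(i) {
      v <- rowMeans(D[, cl$istart[i]:cl$iend[i], drop = FALSE])
      c(mean(v), sd(v))
    }, c(0.0, 0.0)))
    cl$mean_diff <- summ[, 1]
    cl$sd_diff <- summ[, 2]
    cl$d <- cl$mean_diff / cl$sd_diff
    clusters <- data.frame(start_s = tsel[cl$istart], end_s = tsel[cl$iend],
                           n_points = cl$iend - cl$istart + 1L,
                           stat = cl$stat, p = cl$p, sign = cl$sign,
                           mean_diff = cl$mean_diff, sd_diff = cl$sd_diff,
                           d = cl$d)
    clusters <- clusters[order(clusters$p, -abs(clusters$stat)), , drop = FALSE]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(start_s = numeric(), end_s = numeric(),
                           n_points = integer(), stat = numeric(),
                           p = numeric(), sign = numeric(),
                           mean_diff = numeric(), sd_diff = numeric(),
                           d = numeric())
  }
  structure(list(clusters = clusters, t = tobs, times = tsel, n = n,
                 n_perm = n_eff, alpha_point = alpha_point, seed = seed,
                 exhaustive = exhaustive),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> n = %d participants, %d time points, %s permutations\n",
              x$n, length(x$times),
              if (x$exhaustive) sprintf("exhaustive (%d)", x$n_perm)
              else format(x$n_perm)))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    df <- x$clusters
    for (i in seq_len(nrow(df)))
      cat(sprintf("  cluster %.3f-%.3f s: t_cluster = %.2f, p_cluster = %.4g, mean %.3g +/- %.3g, d = %.2f\n",
                  df$start_s[i], df$end_s[i], df$stat[i], df$p[i],
                  df$mean_diff[i], df$sd_diff[i], df$d[i]))
  }
  invisible(x)
}

#' Cohen's d as mean over standard deviation
#'
#' Standardized effect size `d = mu / s` across participants, where `mu` and
#' `s` are the sample mean and sample SD (n-1 denominator) of the
#' participant-level values (typically cluster-extent averages).
#'
#' @param values Numeric vector, one value per participant.
#' @return Cohen's d (scalar).
#' @export
cohens_d <- function(values) {
  stopifnot(length(values) >= 2)
  s <- sd(values)
  if (s == 0) stop("zero standard deviation: Cohen's d undefined")
  mean(values) / s
}
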