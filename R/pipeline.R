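## End-to-end orchestration: synthetic study -> preprocessing ->
## time-frequency/ITPC/regression first-order statistics per participant ->
## cluster-permutation contrasts across participants. Deterministic given
## the config seed.

#' Configuration of an end-to-end analysis run
#'
#' @param session A [session_config()] describing the synthetic study (its
#'   `seed` is overridden by `seed` below so one integer fixes the run).
#' @param n_stimuli_per_condition Stimulus set size per condition (the
#'   emulated experiment used 8 screams and 8 neutral vocalizations).
#' @param bands Power bands analyzed, subset of
#'   `c("delta", "theta", "sigma")`.
#' @param itpc_band Band for phase-coherence analysis (theta: phase-locked
#'   auditory responses live there).
#' @param states Vigilance states analyzed.
#' @param power_window,itpc_window,erp_window Cluster-test windows in
#'   seconds: 0-2 s for power and power-regression series (induced activity
#'   is long-lived), 0-1 s for ERP and ITPC series (evoked, time-locked
#'   activity is shorter).
#' @param n_perm Monte Carlo permutations per cluster test.
#' @param alpha_point Point-wise threshold of the cluster tests.
#' @param db_log10 Use base-10 dB instead of the default `10*ln` convention.
#' @param abs_threshold,flat_threshold Artifact-screening thresholds,
#'   microvolts.
#' @param min_kept_trials Participants with fewer kept trials are excluded
#'   (the emulated study's rule: fewer than 100 unartefacted trials).
#' @param include_erp,include_regression Toggle the ERP and feature-
#'   regression branches.
#' @param seed Master integer seed for the whole run.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(session = session_config(),
                            n_stimuli_per_condition = 8,
                            bands = c("delta", "theta", "sigma"),
                            itpc_band = "theta",
                            states = c("wake", "NREM"),
                            power_window = c(0, 2),
                            itpc_window = c(0, 1),
                            erp_window = c(0, 1),
                            n_perm = 5000,
                            alpha_point = 0.05,
                            db_log10 = FALSE,
                            abs_threshold = 300,
                            flat_threshold = 1,
                            min_kept_trials = 100,
                            include_erp = TRUE,
                            include_regression = TRUE,
                            seed = 1) {
  stopifnot(inherits(session, "session_config"),
            all(bands %in% names(.band_bins)),
            itpc_band %in% names(.band_bins),
            all(states %in% c("wake", "NREM")))
  session$seed <- seed
  cfg <- as.list(environment())
  structure(cfg, class = "analysis_config")
}

## first-order statistics for one participant; returns per-state lists of
## condition-mean band power series, ITPC series, regression beta series,
## and optionally ERP series, each a plain numeric time series after
## channel averaging
.participant_first_order <- function(session, stimuli, cfg) {
  eeg <- rereference_common_average(session$eeg)
  ep <- epoch_eeg(eeg, session$events, window = c(-1, 2))
  ep <- label_epochs(ep, session$hypnogram)
  ep <- reject_artifacts(ep, cfg$abs_threshold, cfg$flat_threshold,
                         min_kept = cfg$min_kept_trials)
  qc <- qc_summary(ep)
  qc$flag_low_trials <- attr(ep, "qc")$flag_low_trials

  need <- sort(unique(c(unlist(.band_bins[cfg$bands]),
                        .band_bins[[cfg$itpc_band]])))
  bank <- build_wavelet_bank(eeg$rate, need)
  ## decimate to the 50 Hz decomposition grid regardless of acquisition rate
  tfr <- tfr_transform(eeg, bank, session$events,
                       downsample = max(1L, as.integer(round(eeg$rate / 50))))
  keep <- ep$info$kept & tfr$valid
  vig <- ep$info$vigilance
  cond <- ep$info$condition
  pw <- baseline_power(power_db(tfr, db_log10 = cfg$db_log10))

  z_map_r <- zscore_features(stimuli$features$roughness)
  z_map_p <- zscore_features(stimuli$features$pitch)
  zi <- match(session$events$stimulus_id, stimuli$features$stimulus_id)

  out <- list(qc = qc, times_tfr = tfr$times)
  for (s in cfg$states) {
    idx <- which(keep & !is.na(vig) & vig == s)
    st <- list(n_trials = length(idx))
    if (length(idx) >= 4) {
      pw_s <- subset_trials(pw, idx)
      tfr_s <- subset_trials(tfr, idx)
      for (b in cfg$bands) {
        bp <- band_average(pw_s, b)              # trials x ch x time
        for (cn in c("scream", "neutral")) {
          tr <- which(cond[idx] == cn)
          st[[paste0("power_", b, "_", cn)]] <-
            if (length(tr)) apply(bp[tr, , , drop = FALSE], 3, mean)
            else rep(NA_real_, dim(bp)[3])
        }
        if (cfg$include_regression) {
          st[[paste0("beta_roughness_", b)]] <- colMeans(
            single_trial_regression(bp, z_map_r[zi[idx]]))
          st[[paste0("beta_pitch_", b)]] <- colMeans(
            single_trial_regression(bp, z_map_p[zi[idx]]))
        }
      }
      for (cn in c("scream", "neutral")) {
        tr <- which(cond[idx] == cn)
        st[[paste0("itpc_", cfg$itpc_band, "_", cn)]] <-
          if (length(tr) >= 2)
            colMeans(band_average(itpc(subset_trials(tfr_s, tr)),
                                  cfg$itpc_band))
          else rep(NA_real_, length(tfr$times))
      }
    }
    out[[s]] <- st
  }

  if (cfg$include_erp) {
    erp_eeg <- bandpass(eeg, 0.1, 30, order = 1)
    ep2 <- epoch_eeg(erp_eeg, session$events, window = c(-1, 2))
    ep2$info <- ep$info                          # reuse labels + rejections
    ep2 <- baseline_correct(ep2, c(-0.5, 0))
    out$times_erp <- ep2$times
    for (s in cfg$states) {
      for (cn in c("scream", "neutral")) {
        tr <- which(keep & !is.na(vig) & vig == s & cond == cn)
        out[[s]][[paste0("erp_", cn)]] <-
          if (length(tr)) apply(ep2$data[tr, , , drop = FALSE], 3, mean)
          else rep(NA_real_, length(ep2$times))
      }
    }
  }
  out
}

#' Run the full synthetic-study analysis
#'
#' Generates the stimulus set and one session per participant, runs
#' preprocessing, time-frequency decomposition, ITPC and single-trial
#' regression per participant, then tests the study's contrasts across
#' participants with cluster-based permutation tests: per state, each band's
#' power per condition against baseline (zero) and screams against neutral;
#' theta ITPC per condition against zero and screams against neutral;
#' roughness and pitch regression slopes against zero; optionally the ERP
#' contrast; and, when both states are analyzed, wake against NREM for
#' theta power and theta ITPC.
#'
#' @param cfg An [analysis_config()].
#' @return An object of class `report_bundle`: `results` (named list of
#'   [paired_cluster_permutation()] results), `first_order` (per-participant
#'   series), `qc` (per-participant data frame), `excluded` (participants
#'   failing the kept-trial rule), `stimuli` (feature table), `config`,
#'   `provenance`.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  stimuli <- generate_stimulus_set(cfg$n_stimuli_per_condition,
                                   seed = cfg$seed)
  n_p <- cfg$session$n_participants
  fo <- vector("list", n_p)
  qc_rows <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    session <- generate_session(cfg$session, stimuli, p)
    fo[[p]] <- .participant_first_order(session, stimuli, cfg)
    q <- fo[[p]]$qc
    qc_rows[[p]] <- data.frame(participant = p, n_events = q$n_events,
                               n_kept = q$n_kept,
                               flag_low_trials = q$flag_low_trials)
  }
  qc <- do.call(rbind, qc_rows)
  excluded <- qc$participant[qc$flag_low_trials]
  use <- setdiff(seq_len(n_p), excluded)
  if (length(use) < 2)
    stop("fewer than 2 participants pass the kept-trial rule")

  gather <- function(state, key) {
    rows <- lapply(use, function(p) fo[[p]][[state]][[key]])
    if (any(vapply(rows, is.null, TRUE))) return(NULL)
    m <- do.call(rbind, rows)
    if (anyNA(m)) return(NULL)
    m
  }
  results <- list()
  seed_i <- 0L
  run_test <- function(a, b, times, window) {
    seed_i <<- seed_i + 1L
    paired_cluster_permutation(a, b, times = times, window = window,
                               alpha_point = cfg$alpha_point,
                               n_perm = cfg$n_perm,
                               seed = cfg$seed + seed_i)
  }
  t_tfr <- fo[[use[1]]]$times_tfr
  for (s in cfg$states) {
    for (b in cfg$bands) {
      sc <- gather(s, paste0("power_", b, "_scream"))
      ne <- gather(s, paste0("power_", b, "_neutral"))
      if (!is.null(sc) && !is.null(ne)) {
        results[[paste0(s, ".power_", b, ".scream_vs_neutral")]] <-
          run_test(sc, ne, t_tfr, cfg$power_window)
        results[[paste0(s, ".power_", b, ".scream_vs_baseline")]] <-
          run_test(sc, NULL, t_tfr, cfg$power_window)
        results[[paste0(s, ".power_", b, ".neutral_vs_baseline")]] <-
          run_test(ne, NULL, t_tfr, cfg$power_window)
      }
      if (cfg$include_regression) {
        for (feat in c("roughness", "pitch")) {
          bt <- gather(s, paste0("beta_", feat, "_", b))
          if (!is.null(bt))
            results[[paste0(s, ".beta_", feat, ".", b)]] <-
              run_test(bt, NULL, t_tfr, cfg$power_window)
        }
      }
    }
    sc <- gather(s, paste0("itpc_", cfg$itpc_band, "_scream"))
    ne <- gather(s, paste0("itpc_", cfg$itpc_band, "_neutral"))
    if (!is.null(sc) && !is.null(ne)) {
      results[[paste0(s, ".itpc_", cfg$itpc_band, ".scream_vs_neutral")]] <-
        run_test(sc, ne, t_tfr, cfg$itpc_window)
      results[[paste0(s, ".itpc_", cfg$itpc_band, ".scream_vs_baseline")]] <-
        run_test(sc, NULL, t_tfr, cfg$itpc_window)
      results[[paste0(s, ".itpc_", cfg$itpc_band, ".neutral_vs_baseline")]] <-
        run_test(ne, NULL, t_tfr, cfg$itpc_window)
    }
    if (cfg$include_erp) {
      sc <- gather(s, "erp_scream"); ne <- gather(s, "erp_neutral")
      if (!is.null(sc) && !is.null(ne))
        results[[paste0(s, ".erp.scream_vs_neutral")]] <-
          run_test(sc, ne, fo[[use[1]]]$times_erp, cfg$erp_window)
    }
  }
  if (all(c("wake", "NREM") %in% cfg$states)) {
    for (key in c(paste0("power_theta"), paste0("itpc_", cfg$itpc_band))) {
      w_s <- gather("wake", paste0(key, "_scream"))
      w_n <- gather("wake", paste0(key, "_neutral"))
      n_s <- gather("NREM", paste0(key, "_scream"))
      n_n <- gather("NREM", paste0(key, "_neutral"))
      if (!is.null(w_s) && !is.null(w_n) && !is.null(n_s) && !is.null(n_n)) {
        win <- if (grepl("^power", key)) cfg$power_window else cfg$itpc_window
        results[[paste0("wake_vs_NREM.", key)]] <-
          run_test((w_s + w_n) / 2, (n_s + n_n) / 2, t_tfr, win)
      }
    }
  }
  structure(list(results = results, first_order = fo, qc = qc,
                 excluded = excluded, stimuli = stimuli$features,
                 config = cfg,
                 provenance = list(
                   seed = cfg$seed, n_perm = cfg$n_perm,
                   package_version = as.character(utils::packageVersion("vocalsleep")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d contrasts, %d participants (%d excluded), seed %d\n",
              length(x$results), nrow(x$qc), length(x$excluded),
              x$provenance$seed))
  for (nm in names(x$results)) {
    cl <- x$results[[nm]]$clusters
    sig <- cl[cl$p < 0.05, , drop = FALSE]
    cat(sprintf("  %-45s %s\n", nm,
                if (nrow(sig) == 0) "no significant cluster"
                else sprintf("cluster %.2f-%.2f s, t_cluster = %.1f, p = %.3g, d = %.2f",
                             sig$start_s[1], sig$end_s[1], sig$stat[1],
                             sig$p[1], sig$d[1])))
  }
  invisible(x)
}

#' Serialize a report bundle to JSON
#'
#' Writes the cluster tables of every contrast plus QC and provenance as
#' deterministic JSON (byte-identical for identical config + seed).
#'
#' @param bundle A `report_bundle`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  obj <- list(
    provenance = bundle$provenance,
    excluded_participants = bundle$excluded,
    qc = bundle$qc,
    contrasts = lapply(bundle$results, function(r)
      list(n = r$n, n_perm = r$n_perm, seed = r$seed,
           clusters = r$clusters)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
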