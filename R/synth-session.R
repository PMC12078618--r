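## Synthetic polysomnography sessions with known ground truth. A session is
## 1/f background noise plus stage-dependent spontaneous sleep oscillations
## (slow waves and spindles in N2/N3), plus per-stimulus injected responses:
##   wake  - an N1-P2-N2 ERP kernel and a phase-locked theta burst;
##   NREM  - an evoked slow wave (P200-N550-P900), a phase-locked theta
##           burst, and a non-phase-locked sigma (spindle-band) burst in a
##           0.6-1.4 s latency window.
## Phase locking uses von Mises phase jitter whose concentration kappa grows
## exponentially with z-scored stimulus roughness; sigma and delta amplitudes
## are linear in z-scored roughness on the (10*ln) dB scale, matching the
## regression model the analysis fits. Every random draw is governed by the
## config seed plus the participant index, so outputs are bit-reproducible.
##
## Components carry scalp topographies (anterior gradient for sleep
## oscillations, central maximum for auditory ERP/theta components): a
## common-average reference removes whatever is common to all channels, so
## responses must vary across the montage to survive re-referencing, exactly
## as real scalp fields do. A stationary multi-sine "tonic" sigma background
## keeps baseline spindle-band power finite and stable, so per-trial dB
## baselining behaves as it does on real (never silent) EEG.

## anterior-posterior row of a 10-20 label: 0 = prefrontal .. 4 = occipital
.montage_row <- function(channels) {
  row_of <- c(Fpz = 0, Fp1 = 0, Fp2 = 0,
              F3 = 1, Fz = 1, F4 = 1, F7 = 1, F8 = 1,
              T3 = 2, C3 = 2, Cz = 2, C4 = 2, T4 = 2,
              P3 = 3, Pz = 3, P4 = 3, T5 = 3, T6 = 3,
              O1 = 4, Oz = 4, O2 = 4)
  r <- row_of[channels]
  r[is.na(r)] <- 2              # unknown labels: treat as central
  unname(r)
}

## component topographies over the montage. "frontal": sleep oscillations
## (slow waves, spindles, evoked NREM responses) peak anteriorly; "central":
## auditory ERP / theta components peak at the vertex.
.montage_gains <- function(channels, type = c("frontal", "central")) {
  type <- match.arg(type)
  r <- .montage_row(channels)
  if (type == "frontal") c(1.8, 1.4, 0.8, 0.4, 0.2)[r + 1]
  else c(0.3, 0.9, 1.5, 0.9, 0.3)[r + 1]
}

#' Configuration of the synthetic session generator
#'
#' Defaults encode the emulated study conditions (500 Hz, 13-channel montage,
#' 5-11 s jitter, blocks of 22 stimuli, 20-s hypnogram epochs) and
#' literature-plausible background sleep EEG (spindle densities 3/min in N2
#' and 1.5/min in N3, 75 microvolt slow waves in N3). Effect sizes are in the
#' units the downstream analysis estimates: `theta_kappa_per_roughness` is
#' the gain of `ln(kappa)` per SD of roughness,
#' `sigma_gain_db_per_sd` / `delta_gain_db_per_sd` are dB (10*ln units) of
#' induced power per SD of roughness.
#'
#' @param n_participants Number of participants the study simulates (>= 2).
#' @param sampling_rate EEG sampling rate, Hz.
#' @param channels Channel labels (13-channel scalp montage by default; a
#'   subset is allowed and proportionally cheaper).
#' @param jitter_range Uniform inter-stimulus jitter range in seconds
#'   (positive, ordered).
#' @param block_size Stimuli per stimulation block.
#' @param n_trials_wake,n_trials_nrem Stimuli presented in the wake and NREM
#'   portions of the session.
#' @param noise_exponent Spectral slope of the 1/f background (power ~
#'   1/f^exponent).
#' @param noise_sd Background noise SD, microvolts.
#' @param theta_freq,theta_amp,theta_latency,theta_width Phase-locked theta
#'   burst: carrier Hz, amplitude (microvolts), Gaussian envelope center and
#'   SD (s).
#' @param theta_kappa_base Von Mises concentration at z-roughness 0.
#' @param theta_kappa_per_roughness Gain of ln(kappa) per SD roughness.
#' @param sigma_freq,sigma_amp Induced spindle-band burst carrier (Hz) and
#'   base amplitude (microvolts, before topographic weighting).
#' @param sigma_tonic_amp Amplitude (microvolts) of the stationary sigma-band
#'   background (one constant-amplitude, random-phase sinusoid per integer
#'   frequency 12-15 Hz per channel). It keeps baseline spindle-band power
#'   finite and stable so trial-wise dB baselining is well conditioned, as on
#'   real EEG; unlike real sigma background it does not wax and wane (the
#'   discrete spontaneous spindles provide that).
#' @param sigma_window Burst latency window (s, Tukey envelope with 0.2 s
#'   cosine edges; flat in between).
#' @param sigma_gain_db_per_sd Induced sigma power slope, dB per SD
#'   roughness.
#' @param sigma_amp_jitter_db Trial-to-trial lognormal amplitude jitter of
#'   the sigma burst, SD in dB.
#' @param delta_gain_db_per_sd Evoked slow-wave power slope, dB per SD
#'   roughness.
#' @param erp_amplitude Scale of the wake ERP kernel (1 = typical
#'   microvolt amplitudes).
#' @param slow_wave_amp Spontaneous N3 slow-wave amplitude, microvolts (N2
#'   uses half).
#' @param sw_rate_n2,sw_rate_n3 Spontaneous slow-wave rates, events/min.
#' @param spindle_rate_n2,spindle_rate_n3 Spontaneous spindle rates,
#'   events/min.
#' @param spindle_amp Spontaneous spindle amplitude, microvolts.
#' @param artifact_fraction Fraction of trials contaminated by a large
#'   (500 microvolt) artifact transient.
#' @param max_duration_s Hard cap on session length; exceeding it is an
#'   explicit error.
#' @param seed Integer seed.
#' @return An object of class `session_config` (a validated list).
#' @export
session_config <- function(n_participants = 15,
                           sampling_rate = 500,
                           channels = c("Fpz", "F3", "Fz", "F4", "T3", "C3",
                                        "Cz", "C4", "T4", "P3", "Pz", "P4",
                                        "Oz"),
                           jitter_range = c(5, 11),
                           block_size = 22,
                           n_trials_wake = 88,
                           n_trials_nrem = 132,
                           noise_exponent = 1,
                           noise_sd = 15,
                           theta_freq = 6, theta_amp = 12,
                           theta_latency = 0.3, theta_width = 0.15,
                           theta_kappa_base = 1,
                           theta_kappa_per_roughness = 0.8,
                           sigma_freq = 13.5, sigma_amp = 40,
                           sigma_tonic_amp = 10,
                           sigma_window = c(0.6, 1.4),
                           sigma_gain_db_per_sd = 1,
                           sigma_amp_jitter_db = 0.5,
                           delta_gain_db_per_sd = 0.1,
                           erp_amplitude = 1,
                           slow_wave_amp = 75,
                           sw_rate_n2 = 3, sw_rate_n3 = 8,
                           spindle_rate_n2 = 3, spindle_rate_n3 = 1.5,
                           spindle_amp = 15,
                           artifact_fraction = 0.02,
                           max_duration_s = Inf,
                           seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_participants >= 2,
            cfg$sampling_rate > 0,
            length(cfg$channels) >= 1, !anyDuplicated(cfg$channels),
            length(cfg$jitter_range) == 2,
            cfg$jitter_range[1] > 0,
            cfg$jitter_range[1] <= cfg$jitter_range[2],
            cfg$n_trials_wake >= 0, cfg$n_trials_nrem >= 0,
            cfg$n_trials_wake + cfg$n_trials_nrem >= 1,
            is.finite(cfg$theta_kappa_per_roughness),
            is.finite(cfg$sigma_gain_db_per_sd),
            is.finite(cfg$delta_gain_db_per_sd),
            cfg$artifact_fraction >= 0, cfg$artifact_fraction <= 1)
  structure(cfg, class = "session_config")
}

## von Mises(mu, kappa) sampler, Best & Fisher (1979)
.rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  out <- numeric(n)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (out + mu + pi) %% (2 * pi) - pi
}

## 1/f^beta Gaussian noise via spectral shaping, scaled to the requested SD
.noise_one_over_f <- function(n, rate, beta, sd_uv) {
  nf <- n %/% 2
  f <- (1:nf) * rate / n
  amp <- f^(-beta / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(ph[nf]))
    if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[n:(n - nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * sd_uv / sd(x)
}

.gauss_bump <- function(t, center, width, amp) {
  amp * exp(-(t - center)^2 / (2 * width^2))
}

## Tukey (cosine-tapered) envelope over [lo, hi] with given edge length
.tukey_env <- function(t, lo, hi, edge = 0.2) {
  env <- numeric(length(t))
  inside <- t >= lo & t <= hi
  env[inside] <- 1
  rise <- t >= lo & t < lo + edge
  env[rise] <- 0.5 * (1 - cos(pi * (t[rise] - lo) / edge))
  fall <- t > hi - edge & t <= hi
  env[fall] <- 0.5 * (1 - cos(pi * (hi - t[fall]) / edge))
  env
}

## wake ERP kernel (N1-P2-N2) and NREM evoked slow wave (P200-N550-P900)
.erp_kernel_wake <- function(t, scale) {
  scale * (.gauss_bump(t, 0.10, 0.03, -5) +
           .gauss_bump(t, 0.20, 0.05, 8) +
           .gauss_bump(t, 0.35, 0.07, -4))
}

.erp_kernel_nrem <- function(t, scale) {
  scale * (.gauss_bump(t, 0.20, 0.06, 15) +
           .gauss_bump(t, 0.55, 0.12, -45) +
           .gauss_bump(t, 0.90, 0.15, 25))
}

#' Generate one synthetic polysomnography session
#'
#' Builds the stimulation timeline (wake block first, then NREM sleep with
#' alternating N2/N3 runs and occasional N1 epochs), synthesizes continuous
#' EEG, and injects the stage-appropriate responses described in
#' [session_config()]. The event table records the true stimulus features;
#' the `truth` table additionally records, per trial, the stage at onset,
#' the injected theta phase and concentration, the injected sigma amplitude
#' deviation (dB), and artifact contamination — the ground truth that oracle
#' tests regress against.
#'
#' @param config A [session_config()].
#' @param stimuli A [generate_stimulus_set()] result (its measured roughness
#'   and pitch drive the injected effects via z-scores over the stimulus
#'   set).
#' @param participant Participant index in `1..n_participants`.
#' @return An object of class `sleep_session`: `eeg` ([eeg_continuous()]),
#'   `events` (data frame), `hypnogram` ([hypnogram()]), `truth` (data
#'   frame), `participant`, `config`.
#' @export
generate_session <- function(config, stimuli, participant = 1) {
  stopifnot(inherits(config, "session_config"),
            inherits(stimuli, "stimulus_set"),
            participant >= 1, participant <= config$n_participants)
  set.seed((config$seed * 100003 + participant * 7919) %% 2147483647L)
  rate <- config$sampling_rate
  feats <- stimuli$features
  dur <- stimuli$specs[[1]]$duration
  z_rough <- zscore_features(feats$roughness)
  z_pitch <- zscore_features(feats$pitch)

  n_w <- config$n_trials_wake
  n_n <- config$n_trials_nrem
  n_tot <- n_w + n_n
  ## balanced stimulus sequence: repeated shuffles of the whole set
  pick <- function(n) {
    if (n == 0) return(integer())
    as.vector(replicate(ceiling(n / nrow(feats)),
                        sample(nrow(feats))))[seq_len(n)]
  }
  stim_idx <- c(pick(n_w), pick(n_n))

  lead_in <- 20
  onsets <- numeric(n_tot)
  t_cur <- lead_in
  epoch_stage <- character()
  if (n_w > 0) {
    for (k in seq_len(n_w)) {
      onsets[k] <- t_cur
      t_cur <- t_cur + dur + runif(1, config$jitter_range[1],
                                   config$jitter_range[2])
    }
    sleep_start <- (floor(t_cur / 20) + 2) * 20     # pad to epoch boundary
    epoch_stage <- rep("W", sleep_start / 20)
    t_cur <- sleep_start + 5
  }
  if (n_n > 0) {
    for (k in seq_len(n_n)) {
      onsets[n_w + k] <- t_cur
      t_cur <- t_cur + dur + runif(1, config$jitter_range[1],
                                   config$jitter_range[2])
    }
  }
  total_s <- (floor((t_cur + 10) / 20) + 1) * 20
  if (total_s > config$max_duration_s)
    stop(sprintf("session too short to place all events: needs %.0f s, cap is %.0f s",
                 total_s, config$max_duration_s))
  n_epochs <- total_s / 20
  ## NREM region: alternating N2/N3 runs with occasional N1 epochs
  while (length(epoch_stage) < n_epochs) {
    if (runif(1) < 0.1) epoch_stage <- c(epoch_stage, "N1")
    st <- if (runif(1) < 0.5) "N2" else "N3"
    epoch_stage <- c(epoch_stage, rep(st, sample(3:8, 1)))
  }
  epoch_stage <- epoch_stage[seq_len(n_epochs)]
  hyp <- hypnogram(epoch_stage)

  n_samp <- as.integer(total_s * rate)
  stage_at <- function(ts) epoch_stage[pmin(floor(ts / 20) + 1L, n_epochs)]

  ## component tracks: sleep oscillations and NREM responses ride a frontal
  ## topography, auditory ERP/theta components a central one, artifacts hit
  ## all channels equally; 1/f noise and the tonic sigma floor are
  ## channel-specific
  track_f <- numeric(n_samp)   # frontal-gradient components
  track_c <- numeric(n_samp)   # central (vertex) components
  track_a <- numeric(n_samp)   # artifacts, no topography
  add_burst <- function(track, t0, dur_s, wave_fun) {
    i0 <- as.integer(round(t0 * rate))
    n_b <- as.integer(round(dur_s * rate))
    if (i0 < 0 || i0 + n_b > n_samp) return(invisible())
    tt <- (0:(n_b - 1)) / rate
    idx <- (i0 + 1L):(i0 + n_b)
    if (track == "f") track_f[idx] <<- track_f[idx] + wave_fun(tt)
    else if (track == "c") track_c[idx] <<- track_c[idx] + wave_fun(tt)
    else track_a[idx] <<- track_a[idx] + wave_fun(tt)
  }
  ## spontaneous slow waves and spindles in N2/N3 epochs
  for (e in seq_len(n_epochs)) {
    st <- epoch_stage[e]
    if (!st %in% c("N2", "N3")) next
    e0 <- (e - 1) * 20
    sw_rate <- if (st == "N3") config$sw_rate_n3 else config$sw_rate_n2
    sw_amp <- if (st == "N3") config$slow_wave_amp else config$slow_wave_amp / 2
    for (k in seq_len(stats::rpois(1, sw_rate / 3))) {
      t0 <- e0 + runif(1, 0, 20 - 1.4)
      add_burst("f", t0, 1.4, function(tt)
        -sw_amp * sin(2 * pi * tt / 1.4) * sin(pi * tt / 1.4)^2)
    }
    sp_rate <- if (st == "N3") config$spindle_rate_n3 else config$spindle_rate_n2
    for (k in seq_len(stats::rpois(1, sp_rate / 3))) {
      t0 <- e0 + runif(1, 0, 20 - 1)
      f_sp <- runif(1, 12, 15)
      ph <- runif(1, 0, 2 * pi)
      add_burst("f", t0, 1, function(tt)
        config$spindle_amp * sin(2 * pi * f_sp * tt + ph) *
          .tukey_env(tt, 0, 1, 0.25))
    }
  }

  ## per-trial injected responses
  stage_trial <- stage_at(onsets)
  z_r <- z_rough[stim_idx]
  theta_kappa <- exp(log(config$theta_kappa_base) +
                     config$theta_kappa_per_roughness * z_r)
  theta_phase <- vapply(theta_kappa, function(k) .rvonmises(1, 0, k), 0.0)
  sigma_db <- config$sigma_gain_db_per_sd * z_r +
    rnorm(n_tot, 0, config$sigma_amp_jitter_db)
  resp_len <- 2.5
  for (k in seq_len(n_tot)) {
    st <- stage_trial[k]
    if (st == "W") {
      add_burst("c", onsets[k], resp_len, function(tt)
        .erp_kernel_wake(tt, config$erp_amplitude))
    } else if (st %in% c("N2", "N3")) {
      amp_delta <- exp(config$delta_gain_db_per_sd * z_r[k] / 20)
      add_burst("f", onsets[k], resp_len, function(tt)
        .erp_kernel_nrem(tt, config$erp_amplitude * amp_delta))
      amp_sigma <- config$sigma_amp * exp(sigma_db[k] / 20)
      ph_s <- runif(1, 0, 2 * pi)
      add_burst("f", onsets[k], resp_len, function(tt)
        amp_sigma * sin(2 * pi * config$sigma_freq * tt + ph_s) *
          .tukey_env(tt, config$sigma_window[1], config$sigma_window[2], 0.2))
    }
    if (st %in% c("W", "N2", "N3")) {
      add_burst("c", onsets[k], resp_len, function(tt)
        config$theta_amp *
          cos(2 * pi * config$theta_freq * (tt - config$theta_latency) +
              theta_phase[k]) *
          exp(-(tt - config$theta_latency)^2 / (2 * config$theta_width^2)))
    }
  }

  ## artifacts: large transient on a random subset of trials
  artifact <- runif(n_tot) < config$artifact_fraction
  for (k in which(artifact)) {
    t0 <- onsets[k] + runif(1, -0.5, 1.5)
    add_burst("a", t0, 0.05, function(tt) 500 * sin(pi * tt / 0.05))
  }

  g_f <- .montage_gains(config$channels, "frontal")
  g_c <- .montage_gains(config$channels, "central")
  t_all <- (0:(n_samp - 1)) / rate
  data <- matrix(0, length(config$channels), n_samp)
  for (i in seq_along(config$channels)) {
    tonic <- numeric(n_samp)
    if (config$sigma_tonic_amp > 0)
      for (f_t in 12:15)
        tonic <- tonic + config$sigma_tonic_amp / 2 *
          sin(2 * pi * f_t * t_all + runif(1, 0, 2 * pi))
    data[i, ] <- g_f[i] * track_f + g_c[i] * track_c + track_a + tonic +
      .noise_one_over_f(n_samp, rate, config$noise_exponent, config$noise_sd)
  }
  eeg <- eeg_continuous(data, rate, config$channels, reference = "Fpz")

  onset_sample <- as.integer(round(onsets * rate))
  events <- data.frame(
    onset_sample = onset_sample,
    stimulus_id = feats$stimulus_id[stim_idx],
    condition = feats$condition[stim_idx],
    roughness = feats$roughness[stim_idx],
    pitch = feats$pitch[stim_idx],
    stringsAsFactors = FALSE)
  truth <- cbind(events,
                 data.frame(z_roughness = z_r,
                            z_pitch = z_pitch[stim_idx],
                            stage = stage_trial,
                            theta_kappa = theta_kappa,
                            theta_phase = theta_phase,
                            sigma_db = sigma_db,
                            artifact = artifact))
  structure(list(eeg = eeg, events = events, hypnogram = hyp, truth = truth,
                 participant = participant, config = config),
            class = "sleep_session")
}

#' @export
print.sleep_session <- function(x, ...) {
  cat(sprintf("<sleep_session> participant %d: %d events, ", x$participant,
              nrow(x$events)))
  print(x$eeg)
  invisible(x)
}

#' Save / load a generator configuration as YAML
#'
#' Serializes every [session_config()] parameter to a YAML file that fully
#' documents a synthetic study, and reads such a file back into a validated
#' config.
#'
#' @param config A [session_config()].
#' @param path YAML file path.
#' @return `path` invisibly (writer); a [session_config()] (reader).
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_session_config
#' @export
read_session_config <- function(path) {
  do.call(session_config, yaml::read_yaml(path))
}

#' Write a session to disk (EDF + TSV tables)
#'
#' Writes the continuous EEG as EDF (with two flat EOG and two flat EMG
#' placeholder channels appended, as a polysomnographic montage expects),
#' the event table and the hypnogram as TSV.
#'
#' @param session A `sleep_session`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix, default `"sub<participant>"`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_session <- function(session, dir,
                          prefix = sprintf("sub%02d", session$participant)) {
  stopifnot(inherits(session, "sleep_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  eeg <- session$eeg
  extra <- matrix(0, 4, ncol(eeg$data))
  aug <- eeg_continuous(rbind(eeg$data, extra), eeg$rate,
                        c(eeg$channels, "EOG1", "EOG2", "EMG1", "EMG2"),
                        eeg$reference)
  paths <- c(edf = file.path(dir, paste0(prefix, ".edf")),
             events = file.path(dir, paste0(prefix, "_events.tsv")),
             hypnogram = file.path(dir, paste0(prefix, "_hypnogram.tsv")))
  write_edf(aug, paths["edf"])
  write_events(session$events, paths["events"])
  write_hypnogram(session$hypnogram, paths["hypnogram"])
  invisible(paths)
}
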