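test_that("stimulus sets are pitch-matched, balanced and RMS-equalized", {
  st <- cached_stimuli()
  expect_length(st$clips, 16)
  expect_equal(sum(st$features$condition == "scream"), 8)
  # pairs share the carrier fundamental
  pitch <- matrix(st$features$pitch, ncol = 2, byrow = TRUE)
  expect_equal(pitch[, 1], pitch[, 2])
  # identical duration and RMS
  expect_true(all(vapply(st$clips, function(cl) length(cl$samples), 0L) == 12000L))
  rms <- vapply(st$clips, function(cl) sqrt(mean(cl$samples^2)), 0.0)
  expect_lt(diff(range(rms)) / mean(rms), 1e-6)
  # screams modulate in the roughness range
  for (sp in st$specs)
    if (sp$condition == "scream")
      expect_true(sp$am_rate >= 30 && sp$am_rate <= 150)
})

test_that("stimulus generation is deterministic and sized by its arguments", {
  a <- generate_stimulus_set(1, seed = 0)
  b <- generate_stimulus_set(1, seed = 0)
  expect_identical(a$clips, b$clips)
  expect_length(a$clips, 2)
  rms <- vapply(a$clips, function(cl) sqrt(mean(cl$samples^2)), 0.0)
  expect_lt(abs(diff(rms)) / mean(rms), 1e-6)
  expect_error(stimulus_spec("x", "scream", 400, am_rate = 10, am_depth = 0.5),
               "30-150")
  expect_error(stimulus_spec("x", "neutral", 400, am_rate = 70, am_depth = 0.5),
               "roughness range")
})

test_that("measured roughness separates conditions in the expected direction", {
  st <- cached_stimuli()
  r <- st$features$roughness
  sc <- st$features$condition == "scream"
  expect_true(all(r[sc][rep(1:8)] > r[!sc][rep(1:8)]))  # pairwise ordering
  expect_gt(mean(r[sc]), mean(r[!sc]))
})

test_that("session timelines respect the jitter bounds within blocks", {
  st <- cached_stimuli()
  cfg <- session_config(n_participants = 2, channels = c("Fz", "Cz"),
                        n_trials_wake = 10, n_trials_nrem = 10, seed = 11)
  s <- generate_session(cfg, st, 1)
  dur <- 0.75
  ioi <- diff(s$events$onset_sample) / cfg$sampling_rate
  # the wake->sleep transition gap is the only interval allowed to exceed it
  within_block <- c(1:9, 11:19)
  expect_true(all(ioi[within_block] >= 5 + dur - 1e-6))
  expect_true(all(ioi[within_block] <= 11 + dur + 1e-6))
  expect_true(all(diff(s$events$onset_sample) > 0))
})

test_that("hypnogram stages agree with the per-trial ground truth labels", {
  st <- cached_stimuli()
  cfg <- session_config(n_participants = 2, channels = c("Fz", "Cz"),
                        n_trials_wake = 8, n_trials_nrem = 20, seed = 12)
  s <- generate_session(cfg, st, 2)
  ep <- label_epochs(epoch_eeg(s$eeg, s$events), s$hypnogram)
  expected <- c(W = "wake", N2 = "NREM", N3 = "NREM")[s$truth$stage]
  agree <- !is.na(ep$info$vigilance) | s$truth$stage == "N1"
  expect_true(all(agree))
  idx <- s$truth$stage != "N1"
  expect_identical(ep$info$vigilance[idx], unname(expected[idx]))
})

test_that("sessions are bit-reproducible and capped by max_duration_s", {
  st <- cached_stimuli()
  cfg <- session_config(n_participants = 2, channels = "Cz",
                        n_trials_wake = 2, n_trials_nrem = 2, seed = 13)
  s1 <- generate_session(cfg, st, 1)
  s2 <- generate_session(cfg, st, 1)
  expect_identical(s1$eeg$data, s2$eeg$data)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$hypnogram$stages, s2$hypnogram$stages)
  s3 <- generate_session(cfg, st, 2)
  expect_false(identical(s1$eeg$data, s3$eeg$data))

  cfg_short <- session_config(n_participants = 2, channels = "Cz",
                              n_trials_wake = 10, n_trials_nrem = 10,
                              max_duration_s = 60, seed = 13)
  expect_error(generate_session(cfg_short, st, 1), "session too short")
})

test_that("background PSD slope tracks the configured 1/f exponent", {
  st <- cached_stimuli()
  for (beta in c(1, 1.5)) {
    cfg <- session_config(n_participants = 2, channels = "Cz",
                          n_trials_wake = 2, n_trials_nrem = 0,
                          noise_exponent = beta, sigma_tonic_amp = 0,
                          erp_amplitude = 0, theta_amp = 0, seed = 14)
    s <- generate_session(cfg, st, 1)
    x <- s$eeg$data[1, ]                      # >= 60 s of background
    sp <- spec.pgram(ts(x, frequency = cfg$sampling_rate), spans = 25,
                     plot = FALSE, taper = 0.1)
    sel <- sp$freq >= 2 & sp$freq <= 40
    slope <- -coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[[2]]
    expect_equal(slope, beta, tolerance = 0.1 * beta)
  }
})

test_that("with zero effect gains the event-locked average converges to zero", {
  st <- cached_stimuli()
  cfg <- session_config(n_participants = 2, channels = c("Fz", "Cz"),
                        n_trials_wake = 0, n_trials_nrem = 60,
                        erp_amplitude = 0, theta_amp = 0, sigma_amp = 0,
                        sw_rate_n2 = 0, sw_rate_n3 = 0,
                        spindle_rate_n2 = 0, spindle_rate_n3 = 0,
                        artifact_fraction = 0, sigma_tonic_amp = 0,
                        theta_kappa_per_roughness = 0,
                        sigma_gain_db_per_sd = 0, delta_gain_db_per_sd = 0,
                        seed = 15)
  s <- generate_session(cfg, st, 1)
  ep <- epoch_eeg(s$eeg, s$events)
  avg <- apply(ep$data[, 1, ], 2, mean)
  sem <- apply(ep$data[, 1, ], 2, sd) / sqrt(nrow(s$events))
  expect_lt(mean(abs(avg) > 3 * sem), 0.05)
})

test_that("the injected ERP is recovered at its true latency", {
  st <- cached_stimuli()
  cfg <- session_config(n_participants = 2, channels = c("Fpz", "Cz"),
                        n_trials_wake = 0, n_trials_nrem = 40,
                        noise_sd = 3, sigma_amp = 0, theta_amp = 0,
                        sw_rate_n2 = 0, sw_rate_n3 = 0,
                        spindle_rate_n2 = 0, spindle_rate_n3 = 0,
                        artifact_fraction = 0, seed = 16)
  s <- generate_session(cfg, st, 1)
  ep <- epoch_eeg(s$eeg, s$events)
  avg <- apply(ep$data[s$truth$stage %in% c("N2", "N3"), 1, ], 2, mean)
  # N550: the largest negative deflection of the evoked slow wave
  expect_equal(ep$times[which.min(avg)], 0.55, tolerance = 0.05)
})

test_that("oracle regression of injected sigma amplitudes recovers the slope", {
  # the generator writes the injected dB deviation per trial; regressing it
  # on z-scored roughness must return the configured gain up to jitter noise
  st <- cached_stimuli()
  slopes <- vapply(1:5, function(seed) {
    cfg <- session_config(n_participants = 2, channels = "Cz",
                          n_trials_wake = 0, n_trials_nrem = 200,
                          sigma_gain_db_per_sd = 0.5, seed = seed)
    s <- generate_session(cfg, st, 1)
    nrem <- s$truth$stage %in% c("N2", "N3")
    coef(lm(s$truth$sigma_db[nrem] ~ s$truth$z_roughness[nrem]))[[2]]
  }, 0.0)
  # jitter SD 0.5 dB over ~200 trials: SE ~ 0.036 per session
  expect_equal(mean(slopes), 0.5, tolerance = 3 * 0.036 / sqrt(5))
})

test_that("von Mises phase concentration follows the Bessel-ratio law", {
  kappas <- c(0.5, 1, 2, 4)
  set.seed(17)
  for (k in kappas) {
    ph <- vocalsleep:::.rvonmises(20000, 0, k)
    expect_lt(abs(Mod(mean(exp(1i * ph))) - besselI(k, 1) / besselI(k, 0)),
              0.02)
  }
})

test_that("measured ITPC of noise-free injected bursts matches the Bessel ratio", {
  st <- cached_stimuli()
  cfg <- session_config(n_participants = 2, channels = "Cz",
                        n_trials_wake = 0, n_trials_nrem = 150,
                        noise_sd = 0.01, sigma_amp = 0, sigma_tonic_amp = 0,
                        erp_amplitude = 0, sw_rate_n2 = 0, sw_rate_n3 = 0,
                        spindle_rate_n2 = 0, spindle_rate_n3 = 0,
                        artifact_fraction = 0,
                        theta_kappa_base = 1.5,
                        theta_kappa_per_roughness = 0, seed = 18)
  s <- generate_session(cfg, st, 1)
  bank <- build_wavelet_bank(500, 6)
  tfr <- tfr_transform(s$eeg, bank, s$events)
  keep <- which(s$truth$stage %in% c("N2", "N3") & tfr$valid)
  it <- itpc(subset_trials(tfr, keep), baseline = NULL)
  at_burst <- it$raw[1, 1, which.min(abs(tfr$times - 0.3))]
  theory <- besselI(1.5, 1) / besselI(1.5, 0)
  # ~150 trials: resultant sampling SD ~ 0.035 plus slight upward bias
  expect_lt(abs(at_burst - theory), 0.08)
})

test_that("injected artifact trials are exactly the rejected ones", {
  st <- cached_stimuli()
  cfg <- session_config(n_participants = 2, channels = c("Fz", "Cz"),
                        n_trials_wake = 0, n_trials_nrem = 40,
                        artifact_fraction = 0.2,
                        sw_rate_n2 = 0, sw_rate_n3 = 0, seed = 19)
  s <- generate_session(cfg, st, 1)
  ep <- reject_artifacts(label_epochs(epoch_eeg(s$eeg, s$events),
                                      s$hypnogram), min_kept = 10)
  flagged <- which(ep$info$reason %in% "amplitude")
  # N1 trials are rejected for stage before amplitude screening sees them
  expect_setequal(flagged, which(s$truth$artifact & s$truth$stage != "N1"))
})
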