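test_that("wavelet FWHM schedule matches its endpoints and midpoint", {
  expect_equal(wavelet_fwhm(1), 1.0)
  expect_equal(wavelet_fwhm(30), 0.33)
  expect_equal(wavelet_fwhm(15.5), 0.665)   # midpoint of the linear schedule
})

test_that("kernel envelopes realize the FWHM schedule within 2%", {
  bank <- build_wavelet_bank(500, c(1, 15, 16, 30))
  measured <- vapply(seq_along(bank$freqs), function(i) {
    env <- Mod(bank$kernels[[i]])
    half <- max(env) / 2
    above <- which(env >= half)
    # linear interpolation at both crossings
    lo <- above[1]; hi <- above[length(above)]
    f_lo <- lo - 1 + (half - env[lo - 1]) / (env[lo] - env[lo - 1])
    f_hi <- hi + (env[hi] - half) / (env[hi] - env[hi + 1])
    (f_hi - f_lo) / bank$rate
  }, 0.0)
  expect_equal(measured, wavelet_fwhm(bank$freqs), tolerance = 0.02)
  # 30 Hz kernel spans ~10 cycles within its FWHM
  expect_equal(0.33 * 30, 9.9)
})

test_that("kernels are unit-energy", {
  bank <- build_wavelet_bank(500, c(2, 10, 25))
  for (k in bank$kernels) expect_equal(sum(Mod(k)^2), 1)
})

test_that("TFR localizes a pure tone in frequency and preserves its phase", {
  eeg <- sine_eeg(10, 20, dur = 30, n_ch = 1)
  bank <- build_wavelet_bank(500, 1:30)
  ev <- regular_events(2, 10, 8)
  tfr <- tfr_transform(eeg, bank, ev)
  pow <- Mod(tfr$values[1, 1, , ])^2
  core <- tfr$times > -1 & tfr$times < 2
  expect_true(all(apply(pow[, core], 2, which.max) == which(tfr$freqs == 10)))

  # centered kernels: phase of a cosine at its peaks is ~0
  t <- seq(0, 30 - 1 / 500, by = 1 / 500)
  eeg_cos <- eeg_continuous(matrix(20 * cos(2 * pi * 5 * t), 1), 500, "Cz")
  tfr5 <- tfr_transform(eeg_cos, bank, ev)
  # peak times of cos(2*pi*5*t): multiples of 0.2 s
  cyc <- (tfr5$times + 10) / 0.2
  sel <- which(abs(cyc - round(cyc)) < 1e-6 & tfr5$times > -1 &
                 tfr5$times < 2)
  ph <- Arg(tfr5$values[1, 1, which(tfr5$freqs == 5), sel])
  expect_true(all(abs(ph) < 0.05))
})

test_that("a stationary sinusoid has time-constant power away from edges", {
  eeg <- sine_eeg(10, 20, dur = 60, n_ch = 1)
  bank <- build_wavelet_bank(500, 8:12)
  ev <- data.frame(onset_sample = 15000L, stimulus_id = "s",
                   condition = "scream", roughness = -1, pitch = 700)
  tfr <- tfr_transform(eeg, bank, ev)
  p_lin <- Mod(tfr$values[1, 1, which(tfr$freqs == 10), ])^2
  expect_lt(sd(p_lin) / mean(p_lin), 0.01)
})

test_that("an amplitude step rises over about one kernel FWHM", {
  # oracle: a unit step convolved with the Gaussian power envelope reaches
  # ~8% and ~92% at -/+ one half-FWHM around the step
  rate <- 500
  t <- seq(0, 40 - 1 / rate, by = 1 / rate)
  x <- 20 * sin(2 * pi * 6 * t) * (t >= 20)
  eeg <- eeg_continuous(matrix(x, 1), rate, "Cz")
  bank <- build_wavelet_bank(rate, 6)
  ev <- data.frame(onset_sample = as.integer(20 * rate), stimulus_id = "s",
                   condition = "scream", roughness = -1, pitch = 700)
  tfr <- tfr_transform(eeg, bank, ev)
  amp <- Mod(tfr$values[1, 1, 1, ])
  plateau <- mean(amp[tfr$times > 1 & tfr$times < 2])
  fw <- wavelet_fwhm(6)
  a_lo <- amp[which.min(abs(tfr$times + fw / 2))] / plateau
  a_hi <- amp[which.min(abs(tfr$times - fw / 2))] / plateau
  # Gaussian amplitude envelope: value at +/- FWHM/2 from a step midpoint
  expect_lt(a_lo, 0.30)
  expect_gt(a_hi, 0.70)
  expect_equal(amp[which.min(abs(tfr$times))] / plateau, 0.5,
               tolerance = 0.1)
})

test_that("trials without full kernel support are flagged invalid", {
  eeg <- sine_eeg(10, 20, dur = 10, n_ch = 1)
  bank <- build_wavelet_bank(500, 1:4)   # 1 Hz kernel: widest support
  ev <- regular_events(2, 3, 3)           # onsets at 3 s and 6 s
  tfr <- tfr_transform(eeg, bank, ev)
  expect_false(tfr$valid[1])   # 3 - 2 s window - ~1.7 s kernel half < 0
  expect_false(tfr$valid[2])   # 6 + 3 + 1.7 > 10 s recording
})

test_that("power_db implements 10*ln with a log10 alternative", {
  tfr <- structure(list(values = array(complex(modulus = c(1, sqrt(exp(1)),
                                                           sqrt(2), 0),
                                               argument = 0), c(1, 1, 1, 4)),
                        times = 1:4, freqs = 1, rate = 50, valid = TRUE,
                        info = NULL),
                   class = "tfr_complex")
  p <- power_db(tfr)
  expect_equal(as.numeric(p$values[1, 1, 1, 1:3]), c(0, 10, 10 * log(2)))
  expect_equal(p$values[1, 1, 1, 3], 6.9315, tolerance = 1e-4)
  # zero modulus is floored, not -Inf
  expect_true(is.finite(p$values[1, 1, 1, 4]))
  p10 <- power_db(tfr, db_log10 = TRUE)
  expect_equal(as.numeric(p10$values[1, 1, 1, 1:3] * log(10)),
               as.numeric(p$values[1, 1, 1, 1:3]))
})

test_that("power baseline correction subtracts the pre-stimulus mean", {
  vals <- array(3, c(2, 1, 1, 100))
  times <- seq(-2, 3, length.out = 100)
  vals[, , , times > 0] <- 5
  p <- structure(list(values = vals, times = times, freqs = 1, rate = 50,
                      valid = c(TRUE, TRUE), info = NULL, db_log10 = FALSE,
                      baseline = NULL),
                 class = "tfr_power")
  out <- baseline_power(p, c(-0.5, 0))
  expect_true(all(out$values[, , , times <= 0 & times >= -0.5] == 0))
  expect_true(all(out$values[, , , times > 0] == 2))
  # constant map -> all zeros
  p$values[] <- 7
  expect_true(all(baseline_power(p)$values == 0))
})

test_that("ITPC matches hand-computed resultant lengths", {
  mk_tfr <- function(phases) {
    structure(list(values = array(complex(modulus = seq_along(phases),
                                          argument = phases),
                                  c(length(phases), 1, 1, 1)),
                   times = 0, freqs = 6, rate = 50, valid = TRUE,
                   info = NULL),
              class = "tfr_complex")
  }
  expect_equal(itpc(mk_tfr(rep(1.3, 5)), baseline = NULL)$raw[1, 1, 1], 1)
  expect_equal(itpc(mk_tfr(c(0.4, 0.4 + pi)), baseline = NULL)$raw[1, 1, 1],
               0, tolerance = 1e-12)
  # {0, pi/2, pi/2, pi/2} -> |1 + 3i| / 4 = sqrt(10) / 4
  expect_equal(itpc(mk_tfr(c(0, pi / 2, pi / 2, pi / 2)),
                    baseline = NULL)$raw[1, 1, 1],
               sqrt(10) / 4)
  # amplitude played no role above: moduli were 1..N by construction
  expect_error(itpc(mk_tfr(0.2)), "at least 2 trials")
})

test_that("ITPC under uniform phases matches the Rayleigh expectation", {
  set.seed(21)
  n <- 20
  draws <- replicate(1000, {
    tfr <- structure(list(values = array(complex(modulus = 1,
                                                 argument = runif(n, -pi, pi)),
                                         c(n, 1, 1, 1)),
                          times = 0, freqs = 6, rate = 50, valid = TRUE,
                          info = NULL),
                     class = "tfr_complex")
    itpc(tfr, baseline = NULL)$raw[1, 1, 1]
  })
  expect_equal(mean(draws), sqrt(pi / (4 * n)), tolerance = 0.1)
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("ITPC baseline correction subtracts per channel and frequency", {
  set.seed(22)
  vals <- array(complex(modulus = 1, argument = runif(3 * 2 * 2 * 50, -pi, pi)),
                c(3, 2, 2, 50))
  vals[, , , 30:40] <- complex(modulus = 1, argument = 0.5)  # locked segment
  tfr <- structure(list(values = vals, times = seq(-1.45, 1, by = 0.05),
                        freqs = c(5, 6), rate = 20, valid = rep(TRUE, 3),
                        info = NULL),
                   class = "tfr_complex")
  out <- itpc(tfr, baseline = c(-1, 0))
  sel <- tfr$times >= -1 & tfr$times <= 0
  expect_lt(max(abs(apply(out$values[, , sel], c(1, 2), mean))), 1e-9)
  expect_true(all(out$values >= -1 & out$values <= 1))
})

test_that("band averages use inclusive integer bins on the 1-Hz grid", {
  vals <- array(0, c(1, 1, 30, 3))
  vals[1, 1, 4:8, ] <- 0:4          # theta bins get 0..4 at every time
  p <- structure(list(values = vals, times = 1:3, freqs = 1:30, rate = 50,
                      valid = TRUE, info = NULL, db_log10 = FALSE,
                      baseline = NULL),
                 class = "tfr_power")
  out <- band_average(p, "theta")
  expect_equal(as.numeric(out), rep(2, 3))   # mean of 0..4 over 5 bins
  p$values[1, 1, 4:8, ] <- 2
  expect_equal(as.numeric(band_average(p, "theta")), rep(2, 3))
  expect_error(band_average(p, "gamma"), "unknown band")
  p_sub <- p; p_sub$values <- p$values[, , 1:10, , drop = FALSE]
  p_sub$freqs <- 1:10
  expect_error(band_average(p_sub, "sigma"), "needs frequency bins")
})

test_that("downsampling commutes with band averaging", {
  set.seed(23)
  vals <- array(rnorm(2 * 1 * 30 * 100), c(2, 1, 30, 100))
  p <- structure(list(values = vals, times = 1:100, freqs = 1:30, rate = 500,
                      valid = c(TRUE, TRUE), info = NULL, db_log10 = FALSE,
                      baseline = NULL),
                 class = "tfr_power")
  p_ds <- p
  p_ds$values <- vals[, , , seq(1, 100, 10), drop = FALSE]
  p_ds$times <- p$times[seq(1, 100, 10)]
  ds_then_band <- band_average(p_ds, "theta")
  band_then_ds <- band_average(p, "theta")[, , seq(1, 100, 10), drop = FALSE]
  expect_lt(max(abs(ds_then_band - band_then_ds)), 1e-9)
})
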