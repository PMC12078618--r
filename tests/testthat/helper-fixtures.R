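# Shared fixtures, generated in code at test time.

# pure tone / AM tone builders
tone_clip <- function(freq, dur = 0.75, rate = 16000, amp = 0.5) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  audio_clip(amp * sin(2 * pi * freq * t), rate)
}

am_clip <- function(carrier, am_rate, depth, dur = 0.75, rate = 16000) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * carrier * t) * (1 + depth * sin(2 * pi * am_rate * t))
  audio_clip(x / max(abs(x)), rate)
}

# small deterministic continuous EEG with known content
sine_eeg <- function(freqs, amps, dur = 10, rate = 500, n_ch = 2,
                     noise_sd = 0) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  base <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  data <- matrix(rep(base, n_ch), nrow = n_ch, byrow = TRUE)
  if (noise_sd > 0) data <- data + matrix(rnorm(length(data), 0, noise_sd),
                                          nrow = n_ch)
  eeg_continuous(data, rate, sprintf("ch%02d", seq_len(n_ch)))
}

# events spaced regularly through a recording (0-based onsets)
regular_events <- function(n, first_s, spacing_s, rate = 500) {
  data.frame(onset_sample = as.integer(round((first_s + (0:(n - 1)) * spacing_s) * rate)),
             stimulus_id = sprintf("s%02d", rep(1:2, length.out = n)),
             condition = rep(c("scream", "neutral"), length.out = n),
             roughness = rep(c(-0.7, -1.9), length.out = n),
             pitch = rep(733, n),
             stringsAsFactors = FALSE)
}

# cached small stimulus set shared across test files (expensive to build)
cached_stimuli <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_stimulus_set(8, seed = 1)
    cache
  }
})
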