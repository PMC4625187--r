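# shared fixtures, built in code

# a 4-channel recording holding the same deterministic signal everywhere
tone_recording <- function(freq, duration = 60, fs = 1024, amplitude = 1,
                           phase = 0, condition = "test") {
  t <- (0:(round(duration * fs) - 1)) / fs
  x <- amplitude * sin(2 * pi * freq * t + phase)
  multisite_recording(cbind(x, x, x, x), fs,
                      meta = list(condition = condition))
}

# a reduced cohort configuration for fast pipeline tests (2 days)
quick_cfg <- function(n_ctr = 2, n_exp = 1, seed = 1) {
  sim_config(n_ctr = n_ctr, n_exp = n_exp, days = 2,
             w_high = list(CTR = c(0.1, 0.9), EXP = c(0.1, 0.1)),
             coupling = list(CTR = c(0.25, 0.6), EXP = c(0.25, 0.25)),
             bias_gain = list(CTR = c(0.2, 1.5), EXP = c(0.2, 0.2)),
             seed = seed)
}

# independent brute-force DFT magnitude computation (test oracle)
brute_force_ap <- function(epoch_matrix, fs, freqs = theta_grid()) {
  N <- nrow(epoch_matrix)
  ap <- numeric(length(freqs))
  for (fi in seq_along(freqs)) {
    k <- freqs[fi] * N / fs
    w <- exp(-2i * pi * k * (0:(N - 1)) / N)
    vals <- apply(epoch_matrix, 2, function(e) abs(sum(e * w))^2)
    ap[fi] <- mean(vals) * 2 / N^2
  }
  ap
}
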