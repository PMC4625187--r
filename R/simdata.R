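#' Narrowband theta oscillator
#'
#' Zero-mean stochastic oscillation with a controllable spectral peak and
#' bandwidth: a second-order resonant (damped AR(2)) process driven by
#' Gaussian innovations, with pole radius `exp(-pi * bandwidth / fs)` so
#' that `bandwidth` is approximately the half-power width of the spectral
#' peak.  `bandwidth = 0` is the degenerate limit: a pure sinusoid with a
#' random phase.  The output is rescaled to the target variance exactly.
#'
#' @param f0 peak frequency in Hz, inside `(0, fs/2)`.
#' @param bandwidth approximate half-power bandwidth in Hz (>= 0).
#' @param duration signal duration in seconds.
#' @param fs sampling rate in Hz.
#' @param variance target variance (arbitrary units^2).
#' @param seed optional integer seed.
#' @return Numeric vector of `round(duration * fs)` samples.
#' @export
make_theta_oscillator <- function(f0, bandwidth, duration, fs,
                                  variance = 1, seed = NULL) {
  if (!is.finite(f0) || f0 <= 0 || f0 >= fs / 2) {
    stop("invalid parameter: f0 must lie in (0, fs/2)")
  }
  if (bandwidth < 0) stop("invalid parameter: bandwidth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  if (bandwidth == 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- sqrt(2 * variance) * cos(2 * pi * f0 * (0:(n - 1)) / fs + phase)
    return(x)
  }
  r <- exp(-pi * bandwidth / fs)
  phi1 <- 2 * r * cos(2 * pi * f0 / fs)
  phi2 <- -r^2
  burn <- min(100000L, ceiling(6 / (1 - r)))
  e <- stats::rnorm(n + burn)
  x <- as.numeric(stats::filter(e, c(phi1, phi2), method = "recursive"))
  x <- x[(burn + 1):(burn + n)]
  x <- x - mean(x)
  x * sqrt(variance / mean(x^2))
}

# Expected fraction of an AR(2) oscillator's variance landing in each
# 4-12 Hz grid bin of the rectangular 2-s-epoch periodogram: the AR(2)
# spectral density convolved with the Fejer kernel of the epoch window.
# Deterministic; cached per (f0, bandwidth, fs, epoch_len).
ar2_bin_fractions <- function(f0, bandwidth, fs, epoch_len = 2) {
  key <- paste("ar2", f0, bandwidth, fs, epoch_len, sep = "_")
  hit <- .thetamaze_cache[[key]]
  if (!is.null(hit)) return(hit)
  grid <- theta_grid()
  if (bandwidth == 0) {
    frac <- as.numeric(grid == grid[which.min(abs(grid - f0))])
  } else {
    N <- round(fs * epoch_len)
    r <- exp(-pi * bandwidth / fs)
    phi1 <- 2 * r * cos(2 * pi * f0 / fs)
    phi2 <- -r^2
    df <- 1 / 128
    f <- seq(df / 2, fs / 2, by = df)
    om <- 2 * pi * f / fs
    S <- 1 / Mod(1 - phi1 * exp(-1i * om) - phi2 * exp(-2i * om))^2
    sigma2 <- 2 * sum(S) * df
    fejer <- function(d) {
      den <- sin(pi * d / fs)^2
      num <- sin(pi * d * N / fs)^2
      ifelse(den < 1e-18, N^2, num / den)
    }
    frac <- vapply(grid, function(fk) {
      (2 / N^2) * sum(S * (fejer(f - fk) + fejer(f + fk))) * df / sigma2
    }, 0)
  }
  .thetamaze_cache[[key]] <- frac
  frac
}

# --- spectral synthesis -----------------------------------------------------
# Stationary Gaussian components of the generator are synthesised in the
# frequency domain from per-line variance vectors ("line spectra"): entry k
# is the variance contributed by frequency k * fs / n.  One complex FFT
# yields two independent real series with the prescribed spectrum, and the
# expected analysis-bin power of any component is just a band sum of its
# line spectrum, which is what makes the coherence calibration exact.

# two independent real zero-mean series (columns) with line spectrum s,
# synthesised at an FFT-friendly length nfft and truncated to n samples
# (a window of a stationary series is stationary with the same spectrum)
synth_pair <- function(s, nfft, n = nfft) {
  half <- length(s)
  Z <- complex(real = numeric(nfft))
  Z[2:(half + 1)] <- sqrt(s / 2) *
    complex(real = stats::rnorm(half), imaginary = stats::rnorm(half))
  y <- stats::fft(Z, inverse = TRUE)[seq_len(n)]
  cbind(Re(y), Im(y)) * sqrt(2)
}

# zero-mean a column and scale it to an exact target variance
exact_var <- function(x, v) {
  x <- x - mean(x)
  if (v <= 0) return(x * 0)
  x * sqrt(v / mean(x^2))
}

# line indices of the frequencies falling in one 0.5-Hz analysis bin
line_freqs <- function(n, fs) (1:floor((n - 1) / 2)) * fs / n

# unit-variance AR(2) (resonant) line spectrum, cached per (n, fs, f0, bw)
ar2_line_spectrum <- function(f0, bandwidth, n, fs) {
  key <- paste("lines", f0, bandwidth, n, fs, sep = "_")
  hit <- .thetamaze_cache[[key]]
  if (!is.null(hit)) return(hit)
  fk <- line_freqs(n, fs)
  r <- exp(-pi * max(bandwidth, 1e-3) / fs)
  phi1 <- 2 * r * cos(2 * pi * f0 / fs)
  phi2 <- -r^2
  om <- 2 * pi * fk / fs
  S <- 1 / Mod(1 - phi1 * exp(-1i * om) - phi2 * exp(-2i * om))^2
  S <- S / sum(S)
  .thetamaze_cache[[key]] <- S
  S
}

# 1/f^alpha-plus-white-floor background line spectrum with unit 4-12 Hz
# band variance, cached per (n, fs, alpha)
background_line_spectrum <- function(n, fs, alpha = 1) {
  key <- paste("bg", n, fs, alpha, sep = "_")
  hit <- .thetamaze_cache[[key]]
  if (!is.null(hit)) return(hit)
  fk <- line_freqs(n, fs)
  S <- fk^(-alpha) + 60^(-alpha)
  S <- S / sum(S[fk >= 4 & fk <= 12])
  .thetamaze_cache[[key]] <- S
  S
}

# expected analysis-bin power of a line spectrum (band sum)
line_bin_power <- function(s, n, fs, bin_freq) {
  fk <- line_freqs(n, fs)
  sum(s[fk >= bin_freq - 0.25 & fk < bin_freq + 0.25])
}

# Solve per-channel shared-driver gains g_i (coherent fraction of power at
# the driver bin) from pairwise magnitude-squared coherence targets
# gamma2_ij = g_i * g_j.  `targets` is either a scalar (all pairs equal)
# or a named vector over the 6 canonical pair labels.
solve_channel_gains <- function(targets) {
  labs <- vapply(region_pairs(), pair_label, "")
  if (length(targets) == 1L && is.null(names(targets))) {
    targets <- stats::setNames(rep(targets, 6), labs)
  }
  if (!all(labs %in% names(targets))) {
    stop("configuration error: coupling must name all pairs: ",
         paste(setdiff(labs, names(targets)), collapse = ", "))
  }
  targets <- targets[labs]
  if (any(targets < 0 | targets > 1)) {
    stop("configuration error: coherence targets must lie in [0, 1]")
  }
  if (all(targets == 0)) return(stats::setNames(rep(0, 4), theta_regions()))
  if (any(targets == 0)) {
    stop("configuration error: mixed zero/nonzero coherence targets are not ",
         "realizable with a single shared driver (pair ",
         labs[which(targets == 0)[1]], ")")
  }
  A <- matrix(0, 6, 4, dimnames = list(labs, theta_regions()))
  for (i in seq_len(6)) A[i, region_pairs()[[i]]] <- 1
  lg <- stats::lsfit(A, log(targets), intercept = FALSE)$coefficients
  g <- pmin(exp(lg), 1)
  fitted <- exp(A %*% log(g))[, 1]
  err <- abs(fitted - targets)
  if (max(err) > 0.05) {
    stop("configuration error: coupling target for pair ",
         labs[which.max(err)], " (", signif(targets[which.max(err)], 3),
         ") is not realizable with a single shared driver (closest ",
         signif(fitted[which.max(err)], 3), ")")
  }
  stats::setNames(as.numeric(g), theta_regions())
}

#' Simulate one trial's 4-channel theta EEG
#'
#' Every channel is the sum of a shared narrowband theta driver (a mixture
#' of a low and a high oscillator, or a single oscillator), independent
#' narrowband noise with the *same* spectral shape, and independent
#' 1/f^alpha background.  Because shared and independent narrowband parts
#' share a spectral shape, the magnitude-squared coherence of a pair
#' (i, j) at the driver bin is `g_i * g_j` with
#' `g = S / (S + N) = SNR / (1 + SNR)`, exactly the shared-source formula;
#' the background's (analytically known) power at the driver bin is
#' subtracted from the independent-noise budget so the target is met even
#' in the presence of background.  Unrealisable coupling requests raise a
#' configuration error naming the offending pair.
#'
#' @param config a [sim_config()]; its schedules supply the drivers,
#'   coupling and SNR for (`group`, `day`, `condition`) unless overridden.
#' @param group `"CTR"` or `"EXP"`.
#' @param day training day (1..days; the probe day uses the last day's
#'   profile).
#' @param trial trial number (metadata only).
#' @param subject subject id (metadata only).
#' @param condition `"basal"`, `"search"`, `"probe"` or other (other
#'   conditions skip the protocol duration checks).
#' @param duration duration in seconds (> 2).
#' @param seed optional integer seed.
#' @param coupling optional override: scalar or named 6-vector of pairwise
#'   coherence targets in `[0, 1]`.
#' @param snr optional override of the shared-theta-to-background power
#'   ratio in the 4-12 Hz band; `Inf` disables the background.
#' @return A `multisite_recording`; the ground-truth driver bin, channel
#'   gains and targets are attached as attribute `"ground_truth"`.
#' @export
simulate_trial_eeg <- function(config = sim_config(), group = "CTR", day = 1,
                               trial = 1, subject = "S01",
                               condition = "search", duration = 60,
                               seed = NULL, coupling = NULL, snr = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (duration <= 2) stop("duration must exceed 2 s (one epoch)")
  day_idx <- min(day, config$days)
  if (day < 1 || day > config$days + 1) stop("day outside the schedule")
  if (!is.null(seed)) set.seed(seed)
  drv <- drivers_for(config, group, day_idx)
  if (is.null(coupling)) {
    coupling <- if (identical(condition, "basal")) config$basal_coupling
                else config$coupling[[group]][day_idx]
  }
  if (is.null(snr)) {
    snr <- if (identical(condition, "basal")) config$basal_snr else config$snr
  }
  fs <- config$fs
  n <- round(duration * fs)
  nfft <- stats::nextn(n, c(2, 3, 5))
  bw <- config$oscillator_bandwidth
  g <- solve_channel_gains(coupling)

  # driver mixture line spectrum: unit total variance
  w <- drv$w / sum(drv$w)
  mix_lines <- 0
  for (j in seq_along(w)) {
    if (w[j] > 0) {
      mix_lines <- mix_lines + w[j] * ar2_line_spectrum(drv$f[j], bw, nfft, fs)
    }
  }
  f_dom <- drv$f[which.max(w)]
  grid <- theta_grid()
  bin_idx <- which.min(abs(grid - f_dom))
  phi <- 0
  for (j in seq_along(w)) {
    phi <- phi + w[j] * ar2_bin_fractions(drv$f[j], bw, fs)[bin_idx]
  }

  bg_lines <- 0
  bg_bin <- 0
  if (is.finite(snr)) {
    bg_lines <- background_line_spectrum(nfft, fs, config$noise_exponent) / snr
    bg_bin <- line_bin_power(bg_lines, nfft, fs, grid[bin_idx])
  }

  # per-channel independent narrowband budget from the coherence target
  narrow_var <- numeric(4)
  for (ch in 1:4) {
    gi <- g[ch]
    if (gi > 0) {
      n_needed <- phi * (1 - gi) / gi   # required independent power at bin
      nv <- (n_needed - bg_bin) / phi
      if (nv < -0.02) {
        stop("configuration error: coupling target for pair ",
             pair_label(c(theta_regions()[ch],
                          theta_regions()[setdiff(1:4, ch)][1])),
             " is unsatisfiable: background power at the driver bin ",
             "already exceeds the independent-noise budget; ",
             "lower the coupling or raise snr")
      }
      narrow_var[ch] <- max(0, nv)
    } else {
      narrow_var[ch] <- 1   # no shared driver: independent theta instead
    }
  }

  # shared driver and per-channel independent narrowband noise, each scaled
  # to its exact target variance so the coherence calibration holds
  # realization by realization; background left at its expected level
  shared <- exact_var(synth_pair(mix_lines, nfft, n)[, 1], 1)
  narrow <- matrix(0, n, 4)
  if (any(narrow_var > 0)) {
    nb <- cbind(synth_pair(mix_lines, nfft, n), synth_pair(mix_lines, nfft, n))
    for (ch in 1:4) narrow[, ch] <- exact_var(nb[, ch], narrow_var[ch])
  }
  samples <- matrix(0, n, 4)
  bg <- if (is.finite(snr)) {
    cbind(synth_pair(bg_lines, nfft, n), synth_pair(bg_lines, nfft, n))
  } else matrix(0, n, 4)
  for (ch in 1:4) {
    base <- if (g[ch] > 0) shared else 0
    samples[, ch] <- (base + narrow[, ch] + bg[, ch]) * config$region_gains[ch]
  }
  rec <- multisite_recording(samples, fs,
                             meta = list(subject = subject, group = group,
                                         day = day, trial = trial,
                                         condition = condition))
  attr(rec, "ground_truth") <- list(driver_freq = f_dom,
                                    driver_bin = grid[bin_idx],
                                    gains = g, coupling = coupling,
                                    snr = snr)
  rec
}

#' Simulate one water-maze swim trial
#'
#' Correlated random walk at constant speed: each time step the heading
#' receives von-Mises-like turning noise and is then pulled toward the
#' bearing to the platform by a fraction `min(1, bias_gain * dt)` of the
#' angular error, so `bias_gain -> Inf` degenerates to a straight approach
#' and `bias_gain = 0` to an unbiased correlated random walk.  The trial
#' ends at platform entry or at `max_duration` (a timeout; the animal is
#' then guided, which the metrics record via the `guided` flag).  In probe
#' mode the platform is absent, the bias points at its remembered
#' location, and the trial lasts exactly `probe_duration`.
#'
#' @param pool a `pool_geometry`.
#' @param bias_gain goal-directedness (1/s, >= 0).
#' @param speed constant swim speed in m/s (> 0).
#' @param max_duration trial limit in seconds.
#' @param dt time step in seconds.
#' @param turn_sd turning-noise intensity in rad/sqrt(s).
#' @param probe logical; probe mode.
#' @param probe_duration probe length in seconds.
#' @param start_angle angle (rad) of the start point on the pool wall;
#'   random if `NULL`.  The first heading faces inward.
#' @param seed optional integer seed.
#' @param meta metadata list for the trajectory.
#' @return A `swim_trajectory`.
#' @export
simulate_swim_trial <- function(pool = pool_geometry(), bias_gain = 0,
                                speed = 0.25, max_duration = 60, dt = 0.1,
                                turn_sd = 1.5, probe = FALSE,
                                probe_duration = 30, start_angle = NULL,
                                seed = NULL, meta = list()) {
  if (speed <= 0) stop("speed must be positive")
  if (bias_gain < 0) stop("bias_gain must be >= 0")
  if (speed * dt > pool$radius) {
    stop("step-size error: speed * dt exceeds the pool radius")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start_angle)) start_angle <- stats::runif(1, 0, 2 * pi)
  dur <- if (probe) probe_duration else max_duration
  nsteps <- round(dur / dt)
  rin <- pool$radius * (1 - 1e-9)
  px <- pool$platform_center[1]; py <- pool$platform_center[2]
  wrap <- function(a) ((a + pi) %% (2 * pi)) - pi
  x <- numeric(nsteps + 1); y <- numeric(nsteps + 1)
  x[1] <- rin * cos(start_angle); y[1] <- rin * sin(start_angle)
  theta <- start_angle + pi + stats::rnorm(1, 0, 0.3)   # facing inward
  pull <- min(1, bias_gain * dt)
  hit <- FALSE
  k <- 1L
  for (i in seq_len(nsteps)) {
    theta <- theta + stats::rnorm(1, 0, turn_sd * sqrt(dt))
    if (bias_gain > 0) {
      theta <- theta + pull * wrap(atan2(py - y[k], px - x[k]) - theta)
    }
    nx <- x[k] + speed * dt * cos(theta)
    ny <- y[k] + speed * dt * sin(theta)
    r <- sqrt(nx^2 + ny^2)
    if (r > rin) {   # bounce inward off the wall
      nx <- nx * rin / r; ny <- ny * rin / r
      theta <- atan2(-ny, -nx) + stats::rnorm(1, 0, 0.5)
    }
    k <- k + 1L
    x[k] <- nx; y[k] <- ny
    if (!probe && (nx - px)^2 + (ny - py)^2 <= pool$platform_radius^2) {
      hit <- TRUE
      break
    }
  }
  meta$probe <- probe
  swim_trajectory(t = (0:(k - 1)) * dt, x = x[1:k], y = y[1:k],
                  pool = pool, meta = meta)
}

#' Cohort simulation configuration
#'
#' All tunable parameters of the synthetic cohort.  The defaults emulate
#' the study conditions: 7 control (CTR) and 6 experimental (EXP)
#' subjects; 6 training days of 1 basal record (60 s) plus 4 search trials
#' (up to 60 s of searching + 15 s on the platform), and a 30-s probe on
#' day 7; EEG sampled at 1024 Hz.  The CTR spectral profile shifts its
#' dominant theta frequency from 7 Hz toward 8 Hz across days (via the
#' low/high driver mixture weights `w_high`) with rising inter-region
#' coherence, while the EXP profile stays flat; CTR swim trials become
#' increasingly goal-directed (`bias_gain`), EXP trials do not.
#'
#' @param fs sampling rate, Hz.
#' @param n_ctr,n_exp subjects per group.
#' @param days training days (the probe day is `days + 1`).
#' @param trials_per_day search trials per day.
#' @param f_low,f_high frequencies (Hz) of the low and high theta drivers.
#' @param w_high per-group vector (length `days`) of the high-driver
#'   mixture weight per day.
#' @param coupling per-group vector (length `days`) of the pairwise
#'   coherence target at the driver bin, in `[0, 1]`.
#' @param oscillator_bandwidth oscillator half-power bandwidth, Hz.
#' @param noise_exponent background slope alpha in 1/f^alpha.
#' @param snr shared-theta to background power ratio in the 4-12 Hz band
#'   during search; `basal_snr`, `basal_coupling` the basal-condition
#'   counterparts.
#' @param swim_speed constant swim speed, m/s.
#' @param swim_dt trajectory time step, s.
#' @param turn_sd turning-noise intensity, rad/sqrt(s).
#' @param bias_gain per-group vector (length `days`) of swim bias gains.
#' @param pool a `pool_geometry`.
#' @param trial_limit search limit, s.
#' @param platform_time time spent on the platform after each trial, s.
#' @param probe_duration probe length, s.
#' @param basal_duration basal record length, s.
#' @param region_gains per-channel amplitude scale (arbitrary units).
#' @param peak_schedule optional per-group vector (length `days`) of a
#'   single dominant frequency per day; overrides the two-driver mixture.
#' @param seed master seed; a fixed seed makes the whole cohort
#'   bit-reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 1024, n_ctr = 7, n_exp = 6, days = 6,
                       trials_per_day = 4, f_low = 7, f_high = 8,
                       w_high = list(CTR = c(0.10, 0.25, 0.45, 0.60, 0.75, 0.90),
                                     EXP = rep(0.10, 6)),
                       coupling = list(CTR = c(0.25, 0.30, 0.40, 0.45, 0.55, 0.60),
                                       EXP = rep(0.25, 6)),
                       oscillator_bandwidth = 0.5, noise_exponent = 1,
                       snr = 3, basal_snr = 1.5, basal_coupling = 0.2,
                       swim_speed = 0.25, swim_dt = 0.1, turn_sd = 1.5,
                       bias_gain = list(CTR = c(0.2, 0.4, 0.7, 1.0, 1.3, 1.5),
                                        EXP = rep(0.2, 6)),
                       pool = pool_geometry(), trial_limit = 60,
                       platform_time = 15, probe_duration = 30,
                       basal_duration = 60,
                       region_gains = c(SUM = 1, MS = 0.8, DG = 1.2, CA1 = 1),
                       peak_schedule = NULL, seed = 1) {
  if (round(fs * 2) != fs * 2) stop("fs x epoch length must be an integer")
  for (f in c(f_low, f_high, unlist(peak_schedule))) {
    if (f < 4 || f > 12) stop("driver frequencies must lie within 4-12 Hz")
  }
  for (gk in c("CTR", "EXP")) {
    for (lst in list(w_high, coupling, bias_gain)) {
      if (length(lst[[gk]]) != days) {
        stop("per-day schedules must have length days = ", days)
      }
    }
    if (any(coupling[[gk]] < 0 | coupling[[gk]] > 1)) {
      stop("coherence targets must lie in [0, 1]")
    }
    if (any(w_high[[gk]] < 0 | w_high[[gk]] > 1)) {
      stop("mixture weights must lie in [0, 1]")
    }
  }
  if (basal_coupling < 0 || basal_coupling > 1) {
    stop("coherence targets must lie in [0, 1]")
  }
  structure(list(fs = fs, n_ctr = n_ctr, n_exp = n_exp, days = days,
                 trials_per_day = trials_per_day, f_low = f_low,
                 f_high = f_high, w_high = w_high, coupling = coupling,
                 oscillator_bandwidth = oscillator_bandwidth,
                 noise_exponent = noise_exponent, snr = snr,
                 basal_snr = basal_snr, basal_coupling = basal_coupling,
                 swim_speed = swim_speed, swim_dt = swim_dt,
                 turn_sd = turn_sd, bias_gain = bias_gain, pool = pool,
                 trial_limit = trial_limit, platform_time = platform_time,
                 probe_duration = probe_duration,
                 basal_duration = basal_duration,
                 region_gains = region_gains,
                 peak_schedule = peak_schedule, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_ctr, " CTR + ", x$n_exp, " EXP subjects, ",
      x$days, " days x ", x$trials_per_day, " trials + probe, fs = ",
      x$fs, " Hz, seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# Driver mixture (frequency, weight) for a group on a given day.
drivers_for <- function(config, group, day) {
  if (!is.null(config$peak_schedule)) {
    return(data.frame(f = config$peak_schedule[[group]][day], w = 1))
  }
  wh <- config$w_high[[group]][day]
  data.frame(f = c(config$f_low, config$f_high), w = c(1 - wh, wh))
}

# Subject table for a config.
cohort_subjects <- function(config) {
  data.frame(
    subject = c(sprintf("CTR%02d", seq_len(config$n_ctr)),
                sprintf("EXP%02d", seq_len(config$n_exp))),
    group = rep(c("CTR", "EXP"), c(config$n_ctr, config$n_exp)),
    stringsAsFactors = FALSE)
}

# Iterate the whole cohort design in a fixed, seed-derived order, calling
# `fun(kind, rec, traj, info)` for every record.  kind is "basal",
# "search" or "probe"; traj is NULL for basal records.  Both
# simulate_cohort() and run_all() use this single generator, so a fixed
# master seed yields bit-identical data on either path.
cohort_iterate <- function(config, fun, platform_eeg = TRUE,
                           conditions = c("basal", "search", "probe")) {
  subjects <- cohort_subjects(config)
  # start positions: one quadrant bisector per trial, same order for every
  # subject within a day, permuted across days
  bisectors <- c(N = pi / 2, E = 0, S = 3 * pi / 2, W = pi)
  start_order <- lapply(seq_len(config$days), function(d) {
    set.seed(derive_seed(config$seed, 999999, d))
    sample(bisectors)
  })
  for (si in seq_len(nrow(subjects))) {
    subj <- subjects$subject[si]
    grp <- subjects$group[si]
    for (day in seq_len(config$days)) {
      if ("basal" %in% conditions) {
        rec <- simulate_trial_eeg(config, grp, day, trial = 0, subject = subj,
                                  condition = "basal",
                                  duration = config$basal_duration,
                                  seed = derive_seed(config$seed, si, day, 0, 1))
        fun("basal", rec, NULL,
            list(subject = subj, group = grp, day = day, trial = 0L))
      }
      if (!"search" %in% conditions) next
      for (tr in seq_len(config$trials_per_day)) {
        traj <- simulate_swim_trial(
          config$pool, bias_gain = config$bias_gain[[grp]][day],
          speed = config$swim_speed, max_duration = config$trial_limit,
          dt = config$swim_dt, turn_sd = config$turn_sd,
          start_angle = start_order[[day]][(tr - 1) %% 4 + 1],
          seed = derive_seed(config$seed, si, day, tr, 2),
          meta = list(subject = subj, group = grp, day = day, trial = tr))
        tm <- escape_latency(traj, max_duration = config$trial_limit)
        dur <- if (platform_eeg) tm$latency + config$platform_time
               else max(tm$latency, 2.5)
        rec <- simulate_trial_eeg(
          config, grp, day, trial = tr, subject = subj,
          condition = "search", duration = dur,
          seed = derive_seed(config$seed, si, day, tr, 3))
        rec$meta$search_latency <- tm$latency
        rec$meta$guided <- tm$guided
        fun("search", rec, traj,
            list(subject = subj, group = grp, day = day, trial = tr,
                 latency = tm$latency, guided = tm$guided))
      }
    }
    # day-7 probe: platform removed, bias at the remembered location
    if (!"probe" %in% conditions) next
    probe_day <- config$days + 1L
    traj <- simulate_swim_trial(
      config$pool, bias_gain = config$bias_gain[[grp]][config$days],
      speed = config$swim_speed, dt = config$swim_dt,
      turn_sd = config$turn_sd, probe = TRUE,
      probe_duration = config$probe_duration,
      seed = derive_seed(config$seed, si, probe_day, 1, 2),
      meta = list(subject = subj, group = grp, day = probe_day,
                  trial = 1L))
    rec <- simulate_trial_eeg(config, grp, probe_day, trial = 1L,
                              subject = subj, condition = "probe",
                              duration = config$probe_duration,
                              seed = derive_seed(config$seed, si, probe_day, 1, 3))
    fun("probe", rec, traj,
        list(subject = subj, group = grp, day = probe_day, trial = 1L))
  }
  invisible(NULL)
}

#' Simulate a full cohort
#'
#' Generates, per subject: one 60-s basal record plus `trials_per_day`
#' search records (EEG duration = escape latency + 15 s on the platform)
#' for each training day, and the day-7 probe (a 30-s record and a 30-s
#' platform-free trajectory).  EEG and trajectory durations agree per
#' trial, and a fixed master seed makes the whole collection
#' bit-reproducible.
#'
#' @param config a [sim_config()].
#' @return An object of class `theta_cohort`: `recordings` (named list of
#'   `multisite_recording`), `trajectories` (named list of
#'   `swim_trajectory`), a `manifest` data frame and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  recordings <- list(); trajectories <- list(); rows <- list()
  collect <- function(kind, rec, traj, info) {
    id <- sprintf("%s_d%d_t%d_%s", info$subject, info$day, info$trial, kind)
    recordings[[id]] <<- rec
    if (!is.null(traj)) trajectories[[id]] <<- traj
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, subject = info$subject, group = info$group, day = info$day,
      trial = info$trial, condition = kind,
      duration = recording_duration(rec),
      latency = if (is.null(info$latency)) NA_real_ else info$latency)
  }
  cohort_iterate(config, collect)
  structure(list(recordings = recordings, trajectories = trajectories,
                 manifest = do.call(rbind, rows), config = config),
            class = "theta_cohort")
}

#' @export
print.theta_cohort <- function(x, ...) {
  cat("<theta_cohort> ", length(unique(x$manifest$subject)), " subjects, ",
      length(x$recordings), " recordings, ", length(x$trajectories),
      " trajectories\n", sep = "")
  invisible(x)
}

#' Save a cohort to a directory of delimited tables
#'
#' Writes one EEG table and (for swim trials) one trajectory table per
#' record, plus a `manifest.tsv` inventory with file names and MD5
#' checksums.
#'
#' @param cohort a `theta_cohort`.
#' @param dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$eeg_file <- paste0(man$id, "_eeg.tsv")
  man$traj_file <- ifelse(man$id %in% names(cohort$trajectories),
                          paste0(man$id, "_traj.tsv"), NA)
  for (i in seq_len(nrow(man))) {
    write_recording(cohort$recordings[[man$id[i]]],
                    file.path(dir, man$eeg_file[i]))
    if (!is.na(man$traj_file[i])) {
      write_trajectory(cohort$trajectories[[man$id[i]]],
                       file.path(dir, man$traj_file[i]))
    }
  }
  man$eeg_md5 <- unname(tools::md5sum(file.path(dir, man$eeg_file)))
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(man)
}
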