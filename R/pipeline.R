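#' Analyse one recording: spectra, peaks and coherences
#'
#' Runs the per-trial analysis chain: 1-100 Hz zero-phase band-pass,
#' 2-s epoching, amplitude-based artifact rejection, absolute and relative
#' power on the 4-12 Hz grid, theta peak frequency, and (when at least two
#' epochs survive) magnitude-squared coherence for all region pairs with
#' their peaks.  For search records only the pre-platform searching period
#' is analysed by default; set `include_platform = TRUE` to keep the 15 s
#' on the platform.
#'
#' @param rec a `multisite_recording`.  For search records the metadata
#'   field `search_latency` (seconds) marks the platform entry.
#' @param band peak/FCP search band in Hz.
#' @param taper `"rect"` or `"hann"`.
#' @param z_threshold artifact-rejection threshold (robust-SD units).
#' @param include_platform keep the on-platform period of search records.
#' @param epoch_len epoch length in seconds.
#' @return A list: `power`, `rp`, `nl_ap`, `peaks`, `coherence` (list of
#'   6 or `NULL`), `coherence_peaks`, `n_epochs`, `excluded` (reason or
#'   `NA`).
#' @export
analyze_recording <- function(rec, band = c(5, 10),
                              taper = c("rect", "hann"), z_threshold = 6,
                              include_platform = FALSE, epoch_len = 2) {
  taper <- match.arg(taper)
  lat <- rec$meta$search_latency
  if (!include_platform && identical(rec$meta$condition, "search") &&
      !is.null(lat)) {
    keep_n <- min(nrow(rec$samples), max(1L, round(lat * rec$fs)))
    rec <- multisite_recording(rec$samples[seq_len(keep_n), , drop = FALSE],
                               rec$fs, meta = c(rec$meta[setdiff(
                                 names(rec$meta), "condition")],
                                 list(condition = "search_pre")),
                               validate = FALSE)
  }
  if (recording_duration(rec) < epoch_len) {
    return(list(power = NULL, excluded = sprintf(
      "record too short for one epoch (%.2f s)", recording_duration(rec))))
  }
  filt <- rec
  filt$samples <- bandpass_filter(rec$samples, rec$fs)
  es <- epoch_signal(filt, epoch_len = epoch_len)
  es <- reject_artifacts(es, z_threshold = z_threshold)
  ps <- absolute_power(es, taper = taper)
  rp <- relative_power(ps)
  out <- list(power = ps, rp = rp, nl_ap = log_absolute_power(ps),
              peaks = peak_frequency(rp, band = band),
              coherence = NULL, coherence_peaks = NULL,
              n_epochs = ps$n_epochs, excluded = NA_character_)
  if (sum(es$keep) >= 2) {
    out$coherence <- coherence_all(es, taper = taper)
    out$coherence_peaks <- lapply(out$coherence, coherence_peak, band = band)
  }
  out
}

#' Daily peak frequency
#'
#' The daily peak frequency of a region is the mean of the four trial
#' peaks of that day.
#'
#' @param trial_peaks numeric vector of per-trial peak frequencies (Hz).
#' @return Mean peak frequency in Hz.
#' @export
daily_peak_frequency <- function(trial_peaks) {
  mean(trial_peaks, na.rm = TRUE)
}

# epoch-count-weighted mean coherence across trials of one day
weighted_daily_msc <- function(msc_list, n_epochs, weighted = TRUE) {
  w <- if (weighted) n_epochs else rep(1, length(n_epochs))
  m <- do.call(cbind, msc_list)
  as.numeric(m %*% (w / sum(w)))
}

#' Run the full simulate-and-analyse pipeline
#'
#' Simulates a cohort under `config` and runs every analysis stage,
#' per-trial records being analysed and discarded on the fly so a full
#' cohort fits comfortably in memory.  The report contains the
#' machine-readable twins of the study's summary tables: relative power by
#' region, day and frequency; coherence by pair, day and frequency (daily
#' values are epoch-count-weighted means over the four trials);
#' daily peak frequencies with their cross-region Pearson correlations;
#' behavioural metrics (latency, path length, velocity, probe quadrant
#' distances); and the statistical battery.
#'
#' @param config a [sim_config()].
#' @param what subset of c("spectral", "coherence", "behavior", "stats")
#'   to compute; "stats" implies "spectral" and "behavior".
#' @param band analysis band in Hz for peaks and FCP.
#' @param gg use Greenhouse-Geisser corrected p-values for the
#'   repeated-measures ANOVAs (recommended for inference; the uncorrected
#'   F and df are always reported).
#' @param include_platform analyse the on-platform EEG of search trials.
#' @param days_subset optional day subset (e.g. `c(1, 2, 5, 6)`) for an
#'   additional RM-ANOVA pass, mirroring the acquisition/consolidation
#'   contrast.
#' @param conditions which protocol conditions to simulate and analyse
#'   (default all three); e.g. `"search"` alone for a spectra-only power
#'   analysis, skipping the basal and probe records entirely.
#' @param trim_generation when the platform period is not analysed
#'   (`include_platform = FALSE`), generate search EEG only up to platform
#'   entry instead of simulating the 15 s on the platform that would be
#'   discarded anyway.  Analysis results are equivalent; set `FALSE` to
#'   generate the full protocol-length records.
#' @return An object of class `theta_report`; see Details.
#' @export
run_all <- function(config = sim_config(),
                    what = c("spectral", "coherence", "behavior", "stats"),
                    band = c(5, 10), gg = TRUE, include_platform = FALSE,
                    days_subset = NULL,
                    conditions = c("basal", "search", "probe"),
                    trim_generation = !include_platform) {
  do_spec <- "spectral" %in% what || "stats" %in% what
  do_coh <- "coherence" %in% what
  do_beh <- "behavior" %in% what || "stats" %in% what
  do_stats <- "stats" %in% what
  sp_rows <- list(); coh_rows <- list(); pk_rows <- list()
  beh_rows <- list(); probe_rows <- list(); log_rows <- list()
  fcp_rows <- list()
  n_in <- 0L

  cb <- function(kind, rec, traj, info) {
    n_in <<- n_in + 1L
    if (do_beh && !is.null(traj)) {
      if (kind == "probe") {
        qd <- quadrant_distances(traj)
        probe_rows[[length(probe_rows) + 1L]] <<- data.frame(
          subject = info$subject, group = info$group,
          quadrant = names(qd$distances), distance = unname(qd$distances),
          total = qd$total)
      } else {
        tm <- escape_latency(traj, max_duration = 60)
        beh_rows[[length(beh_rows) + 1L]] <<- data.frame(
          subject = info$subject, group = info$group, day = info$day,
          trial = info$trial, latency = tm$latency,
          path_length = tm$path_length, velocity = tm$mean_velocity,
          guided = tm$guided)
      }
    }
    if (!(do_spec || do_coh)) return(invisible())
    an <- tryCatch(
      analyze_recording(rec, band = band,
                        include_platform = include_platform),
      error = function(e) list(power = NULL, excluded = conditionMessage(e)))
    if (is.null(an$power)) {
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        stage = "spectral", subject = info$subject, day = info$day,
        trial = info$trial, condition = kind, action = "excluded",
        reason = an$excluded)
      return(invisible())
    }
    if (do_spec) {
      nf <- length(theta_grid())
      for (ch in seq_len(4)) {
        sp_rows[[length(sp_rows) + 1L]] <<- data.frame(
          subject = info$subject, group = info$group, day = info$day,
          trial = info$trial, region = theta_regions()[ch],
          condition = kind, freq = theta_grid(),
          ap = an$power$ap[, ch], nl_ap = an$nl_ap[, ch],
          rp = an$rp$rp[, ch])
      }
      pk_rows[[length(pk_rows) + 1L]] <<- data.frame(
        subject = info$subject, group = info$group, day = info$day,
        trial = info$trial, condition = kind,
        region = an$peaks$channel, peak_freq = an$peaks$peak_freq,
        peak_rp = an$peaks$peak_rp)
    }
    if (do_coh) {
      if (is.null(an$coherence)) {
        log_rows[[length(log_rows) + 1L]] <<- data.frame(
          stage = "coherence", subject = info$subject, day = info$day,
          trial = info$trial, condition = kind, action = "excluded",
          reason = "fewer than 2 kept epochs")
      } else {
        for (pl in names(an$coherence)) {
          cs <- an$coherence[[pl]]
          cp <- an$coherence_peaks[[pl]]
          coh_rows[[length(coh_rows) + 1L]] <<- data.frame(
            subject = info$subject, group = info$group, day = info$day,
            trial = info$trial, condition = kind, pair = pl,
            freq = cs$freqs, msc = cs$msc, n_epochs = cs$n_epochs)
          fcp_rows[[length(fcp_rows) + 1L]] <<- data.frame(
            subject = info$subject, group = info$group, day = info$day,
            trial = info$trial, condition = kind, pair = pl,
            fcp = cp$fcp, magnitude = cp$magnitude,
            n_epochs = cs$n_epochs)
        }
      }
    }
    invisible()
  }
  cohort_iterate(config, cb, platform_eeg = !trim_generation,
                 conditions = conditions)

  rep <- list(config = config,
              spectra = if (length(sp_rows)) do.call(rbind, sp_rows),
              peaks = if (length(pk_rows)) do.call(rbind, pk_rows),
              coherence = if (length(coh_rows)) do.call(rbind, coh_rows),
              coherence_peaks = if (length(fcp_rows)) do.call(rbind, fcp_rows),
              behavior = if (length(beh_rows)) do.call(rbind, beh_rows),
              probe = if (length(probe_rows)) do.call(rbind, probe_rows),
              log = if (length(log_rows)) do.call(rbind, log_rows)
                    else data.frame(),
              n_records_in = n_in)

  # daily aggregates
  if (!is.null(rep$peaks)) {
    srch <- rep$peaks[rep$peaks$condition == "search", ]
    rep$daily_peaks <- stats::aggregate(
      peak_freq ~ subject + group + day + region, data = srch,
      FUN = daily_peak_frequency)
  }
  if (!is.null(rep$coherence)) {
    srch <- rep$coherence[rep$coherence$condition == "search", ]
    wm <- function(d) {
      stats::aggregate(cbind(wmsc = msc * n_epochs, w = n_epochs) ~
                         subject + group + day + pair + freq,
                       data = d, FUN = sum)
    }
    agg <- wm(srch)
    agg$msc <- agg$wmsc / agg$w
    rep$daily_coherence <- agg[, c("subject", "group", "day", "pair",
                                   "freq", "msc")]
  }

  if (do_stats) rep$stats <- pipeline_stats(rep, band = band, gg = gg,
                                            days_subset = days_subset)
  structure(rep, class = "theta_report")
}

# The statistical battery over a report's tidy tables.
pipeline_stats <- function(rep, band = c(5, 10), gg = TRUE,
                           days_subset = NULL) {
  out <- list()
  freqs_in_band <- theta_grid()[theta_grid() >= band[1] &
                                theta_grid() <= band[2]]
  if (!is.null(rep$spectra)) {
    srch <- rep$spectra[rep$spectra$condition == "search" &
                        rep$spectra$freq %in% freqs_in_band, ]
    for (grp in unique(srch$group)) {
      for (reg in theta_regions()) {
        d <- srch[srch$group == grp & srch$region == reg, ]
        key <- paste0("rp_rm_anova_", grp, "_", reg)
        out[[key]] <- tryCatch(
          rm_anova(d, dv = "rp", subject = "subject",
                   within = c("day", "freq"), gg = gg),
          error = function(e) conditionMessage(e))
        if (!is.null(days_subset)) {
          out[[paste0(key, "_subset")]] <- tryCatch(
            rm_anova(d, dv = "rp", subject = "subject",
                     within = c("day", "freq"), days = days_subset, gg = gg),
            error = function(e) conditionMessage(e))
        }
      }
    }
  }
  if (!is.null(rep$daily_peaks)) {
    for (grp in unique(rep$daily_peaks$group)) {
      dsub <- rep$daily_peaks[rep$daily_peaks$group == grp, ]
      cors <- list()
      for (pr in region_pairs()) {
        a <- dsub[dsub$region == pr[1], ]
        b <- dsub[dsub$region == pr[2], ]
        key <- paste(a$subject, a$day)
        b <- b[match(key, paste(b$subject, b$day)), ]
        cors[[pair_label(pr)]] <- tryCatch(
          peak_frequency_correlation(a$peak_freq, b$peak_freq, pair = pr),
          error = function(e) conditionMessage(e))
      }
      out[[paste0("peak_correlations_", grp)]] <- cors
    }
  }
  if (!is.null(rep$behavior)) {
    daily <- stats::aggregate(cbind(latency, path_length, velocity) ~
                                subject + group + day,
                              data = rep$behavior, FUN = mean)
    for (grp in unique(daily$group)) {
      d <- daily[daily$group == grp, ]
      tabs <- list(latency_friedman = stats::xtabs(latency ~ subject + day,
                                                   data = d),
                   distance_blocked_anova = stats::xtabs(
                     path_length ~ subject + day, data = d),
                   velocity_blocked_anova = stats::xtabs(
                     velocity ~ subject + day, data = d))
      for (nm in names(tabs)) {
        m <- matrix(tabs[[nm]], nrow = nrow(tabs[[nm]]),
                    dimnames = dimnames(tabs[[nm]]))
        fn <- if (nm == "latency_friedman") friedman_rank_test
              else blocked_anova_tukey
        out[[paste0(nm, "_", grp)]] <-
          tryCatch(fn(m), error = function(e) conditionMessage(e))
      }
    }
    if (length(unique(daily$group)) == 2) {
      for (day in sort(unique(daily$day))) {
        a <- daily$latency[daily$group == "CTR" & daily$day == day]
        b <- daily$latency[daily$group == "EXP" & daily$day == day]
        out[[paste0("latency_mann_whitney_day", day)]] <-
          tryCatch(mann_whitney(b, a), error = function(e) conditionMessage(e))
      }
    }
  }
  out
}

#' @export
print.theta_report <- function(x, ...) {
  cat("<theta_report> ", x$n_records_in, " records analysed",
      if (nrow(x$log)) paste0(" (", nrow(x$log), " exclusions logged)"),
      "\n", sep = "")
  if (!is.null(x$spectra)) {
    cat("  spectra: ", nrow(x$spectra), " rows (",
        length(unique(x$spectra$subject)), " subjects x ",
        length(unique(x$spectra$day)), " days)\n", sep = "")
  }
  if (!is.null(x$coherence)) {
    cat("  coherence: ", nrow(x$coherence), " rows, ",
        length(unique(x$coherence$pair)), " pairs\n", sep = "")
  }
  if (!is.null(x$behavior)) {
    dd <- stats::aggregate(latency ~ group + day, data = x$behavior,
                           FUN = mean)
    for (g in unique(dd$group)) {
      cat("  mean latency ", g, ": ",
          paste(sprintf("d%d %.1fs", dd$day[dd$group == g],
                        dd$latency[dd$group == g]), collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write the report's tidy tables to a directory
#'
#' One tab-separated file per table (`spectra.tsv`, `peaks.tsv`,
#' `coherence.tsv`, `coherence_peaks.tsv`, `behavior.tsv`, `probe.tsv`,
#' `log.tsv`), the machine-readable twins of the study's tables and
#' figure panels.
#'
#' @param rep a `theta_report`.
#' @param dir output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(rep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in c("spectra", "peaks", "coherence", "coherence_peaks",
               "behavior", "probe", "daily_peaks", "daily_coherence",
               "log")) {
    if (!is.null(rep[[nm]]) && nrow(rep[[nm]])) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(rep[[nm]], f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}
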