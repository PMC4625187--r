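#' Multi-site EEG recording
#'
#' Container for one trial's 4-channel EEG: a time x 4 sample matrix with
#' sampling rate and study metadata (subject, group, day, trial, condition).
#' Channels are stored in the canonical order SUM, MS, DG, CA1.
#'
#' Durations are validated against the study protocol: a basal record is
#' 60 s of awake immobility, a search record is at most 75 s (up to 60 s of
#' searching plus 15 s on the platform) and a probe record is 30 s.  Records
#' with other conditions (e.g. synthetic calibration signals) are exempt.
#'
#' @param samples numeric matrix, time in rows, one column per channel.
#' @param fs sampling rate in Hz.
#' @param channel_labels channel names; must be a permutation of
#'   `theta_regions()`.  Columns are reordered to canonical order.
#' @param meta list of metadata: `subject`, `group` ("CTR"/"EXP"), `day`,
#'   `trial`, `condition` ("basal", "search", "probe", or other).
#' @param validate logical; run invariant checks.
#' @return An object of class `multisite_recording`.
#' @export
multisite_recording <- function(samples, fs, channel_labels = theta_regions(),
                                meta = list(), validate = TRUE) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 4L) {
    stop("recording must have exactly 4 channels, got ", ncol(samples))
  }
  if (!setequal(channel_labels, theta_regions())) {
    stop("channel labels must be a permutation of ",
         paste(theta_regions(), collapse = ", "))
  }
  samples <- samples[, match(theta_regions(), channel_labels), drop = FALSE]
  colnames(samples) <- theta_regions()
  rec <- structure(list(samples = samples, fs = fs, meta = meta),
                   class = "multisite_recording")
  if (validate) validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (anyNA(rec$samples)) {
    bad <- which(rowSums(is.na(rec$samples)) > 0)
    stop("recording contains NA/NaN samples (first bad row ", bad[1], ")")
  }
  if (!is.numeric(rec$fs) || rec$fs <= 0) stop("fs must be positive")
  dur <- recording_duration(rec)
  cond <- rec$meta$condition
  if (!is.null(cond)) {
    if (identical(cond, "basal") && abs(dur - 60) > 1 / rec$fs) {
      stop("basal recording must last 60 s, got ", signif(dur, 4), " s")
    }
    if (identical(cond, "search") && dur > 75 + 1 / rec$fs) {
      stop("search recording must last at most 75 s, got ", signif(dur, 4), " s")
    }
  }
  invisible(rec)
}

#' @export
print.multisite_recording <- function(x, ...) {
  m <- x$meta
  cat("<multisite_recording> ", nrow(x$samples), " samples x 4 channels @ ",
      x$fs, " Hz (", signif(recording_duration(x), 4), " s)\n", sep = "")
  if (length(m)) {
    cat("  ", paste(names(m), unlist(lapply(m, format)), sep = "=",
                    collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `multisite_recording`.
#' @return duration in seconds (`n / fs`).
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Write / read a recording as a delimited text table
#'
#' The on-disk format is tab-separated with a commented header carrying the
#' metadata (`#key\tvalue` lines), then a header row `time SUM MS DG CA1`
#' and one row per sample.  Samples are printed with 17 significant digits
#' so that `read_recording(write_recording(x))` restores the sample matrix
#' bit-identically.
#'
#' @param rec a `multisite_recording`.
#' @param path file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `multisite_recording`.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(rec$meta)) {
    writeLines(sprintf("#%s\t%s", k, format(rec$meta[[k]])), con)
  }
  writeLines(sprintf("#fs\t%.17g", rec$fs), con)
  writeLines(paste(c("time", colnames(rec$samples)), collapse = "\t"), con)
  tt <- (seq_len(nrow(rec$samples)) - 1) / rec$fs
  lines <- sprintf("%.17g\t%.17g\t%.17g\t%.17g\t%.17g",
                   tt, rec$samples[, 1], rec$samples[, 2],
                   rec$samples[, 3], rec$samples[, 4])
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  fs <- NULL
  for (h in lines[hdr]) {
    kv <- strsplit(sub("^#", "", h), "\t")[[1]]
    if (kv[1] == "fs") fs <- as.numeric(kv[2]) else meta[[kv[1]]] <- kv[2]
  }
  if (is.null(fs)) stop("schema error: no #fs header line")
  body <- lines[!hdr]
  cols <- strsplit(body[1], "\t")[[1]]
  if (length(cols) != 5L || cols[1] != "time") {
    stop("schema error: expected columns time + 4 channels, got ",
         length(cols) - 1, " channels")
  }
  if (!setequal(cols[-1], theta_regions())) {
    stop("schema error: channel labels must be ",
         paste(theta_regions(), collapse = ", "))
  }
  dat <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = cols, colClasses = "numeric")
  if (anyNA(dat)) {
    stop("schema error: NaN at row ", which(rowSums(is.na(dat)) > 0)[1])
  }
  dt <- diff(dat$time)
  if (any(dt <= 0)) {
    stop("schema error: non-monotone time at row ", which(dt <= 0)[1] + 1)
  }
  for (k in c("day", "trial")) {
    if (!is.null(meta[[k]])) meta[[k]] <- as.integer(meta[[k]])
  }
  multisite_recording(as.matrix(dat[, cols[-1]]), fs = fs,
                      channel_labels = cols[-1], meta = meta)
}
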