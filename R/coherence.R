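#' Magnitude-squared coherence between two recording sites
#'
#' Welch-style estimator on the same kept 2-s epochs used for the power
#' spectra: `msc(f) = |mean(X Y*)|^2 / (mean|X|^2 mean|Y|^2)`, averaged
#' over epochs and restricted to the 4-12 Hz grid.  At least two kept
#' epochs are required (the single-segment estimate is identically 1).
#' The pair is stored in canonical (alphabetical) order, so (MS, CA1) and
#' (CA1, MS) denote the same pair and yield identical results.
#'
#' @param x a `multisite_recording` or an `epoch_set` (use an epoch set to
#'   share epoching/rejection with the spectral analysis).
#' @param pair character vector of two region labels.
#' @param epoch_len epoch length in seconds (used when `x` is a recording).
#' @param taper `"rect"` or `"hann"`.
#' @return An object of class `coherence_spectrum`: `pair`, `freqs`,
#'   `msc` (17 values in `[0,1]`), `n_epochs`.
#' @export
coherence_spectrum <- function(x, pair, epoch_len = 2,
                               taper = c("rect", "hann")) {
  taper <- match.arg(taper)
  es <- if (inherits(x, "multisite_recording")) epoch_signal(x, epoch_len)
        else if (inherits(x, "epoch_set")) x
        else stop("x must be a multisite_recording or epoch_set")
  pair <- sort(as.character(pair))
  miss <- setdiff(pair, theta_regions())
  if (length(pair) != 2L || length(miss)) {
    stop("schema error: pair must be two of ",
         paste(theta_regions(), collapse = ", "),
         if (length(miss)) paste0(" (unknown: ", paste(miss, collapse = ", "), ")"))
  }
  if (sum(es$keep) < 2L) {
    stop("insufficient epochs for coherence: need >= 2 kept epochs, have ",
         sum(es$keep))
  }
  X <- epoch_dft(es, taper)
  ia <- match(pair[1], theta_regions())
  ib <- match(pair[2], theta_regions())
  A <- X[, , ia]; B <- X[, , ib]
  sxy <- rowMeans(A * Conj(B))
  sxx <- rowMeans(abs(A)^2)
  syy <- rowMeans(abs(B)^2)
  den <- sxx * syy
  msc <- ifelse(den > 0, Mod(sxy)^2 / den, 0)
  msc <- pmin(1, pmax(0, msc))   # guard floating-point overshoot only
  structure(list(pair = pair, freqs = theta_grid(), msc = msc,
                 n_epochs = dim(X)[2], taper = taper, meta = es$meta),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat("<coherence_spectrum> ", pair_label(x$pair), ", ", x$n_epochs,
      " epochs; peak ", signif(max(x$msc), 3), " at ",
      x$freqs[which.max(x$msc)], " Hz\n", sep = "")
  invisible(x)
}

#' Coherence spectra for all region pairs
#'
#' @param x a `multisite_recording` or `epoch_set`.
#' @param pairs `"all"` or a list of 2-element character vectors.
#' @param ... passed to [coherence_spectrum()].
#' @return Named list of `coherence_spectrum` objects (names like
#'   `"CA1-MS"`).
#' @export
coherence_all <- function(x, pairs = "all", ...) {
  if (identical(pairs, "all")) pairs <- region_pairs()
  es <- if (inherits(x, "multisite_recording")) epoch_signal(x) else x
  out <- lapply(pairs, function(p) coherence_spectrum(es, p, ...))
  names(out) <- vapply(pairs, pair_label, "")
  out
}

#' Frequency and magnitude of the coherence peak
#'
#' The grid frequency at which the coherence is maximal within a band
#' (default 5-10 Hz, matching the relative-power comparisons) -- the
#' frequency of the coherence peak (FCP) -- together with the coherence
#' magnitude there.  Ties resolve to the lowest frequency.
#'
#' @param cs a `coherence_spectrum`.
#' @param band inclusive search band in Hz.
#' @return An object of class `coherence_peak`: `pair`, `fcp`,
#'   `magnitude`, `band`.
#' @export
coherence_peak <- function(cs, band = c(5, 10)) {
  stopifnot(inherits(cs, "coherence_spectrum"))
  freqs <- cs$freqs
  if (band[1] < freqs[1] || band[2] > freqs[length(freqs)]) {
    stop("band must lie within the 4-12 Hz grid")
  }
  sel <- which(freqs >= band[1] & freqs <= band[2])
  i <- sel[which.max(cs$msc[sel])]
  structure(list(pair = cs$pair, fcp = freqs[i], magnitude = cs$msc[i],
                 band = band),
            class = "coherence_peak")
}

#' @export
print.coherence_peak <- function(x, ...) {
  cat("<coherence_peak> ", pair_label(x$pair), ": FCP ", x$fcp,
      " Hz, magnitude ", signif(x$magnitude, 3), "\n", sep = "")
  invisible(x)
}

#' Pearson correlation of daily peak frequencies between two regions
#'
#' Correlates paired per-(subject, day) peak frequencies of two regions
#' across all training days, with the exact two-sided p-value from the
#' t transform.  A sample with zero variance in either region raises an
#' explicit undefined-correlation error rather than returning `NaN`.
#'
#' @param daily_peaks_a,daily_peaks_b numeric vectors of daily peak
#'   frequencies, paired per (subject, day); length >= 3.
#' @param pair optional character vector of the two region labels, for
#'   labelling.
#' @return A `theta_test` with fields `r`, `p`, `n`.
#' @export
peak_frequency_correlation <- function(daily_peaks_a, daily_peaks_b,
                                       pair = NULL) {
  a <- as.numeric(daily_peaks_a); b <- as.numeric(daily_peaks_b)
  if (length(a) != length(b)) stop("peak series must be paired (equal length)")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("need at least 3 paired (subject, day) points, have ", n)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("undefined correlation: zero variance in ",
         if (stats::var(a) == 0) "first" else "second", " peak series")
  }
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  theta_test(method = "Pearson correlation of peak frequencies",
             statistic = c(r = unname(ct$estimate)),
             df = unname(ct$parameter), p = ct$p.value, n = n,
             extra = list(pair = pair, t = unname(ct$statistic)))
}
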