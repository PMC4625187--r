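#' Zero-phase band-pass filter
#'
#' Frequency-domain band-pass with raised-cosine transition bands, applied
#' symmetrically (zero phase).  With the default 1-100 Hz band the response
#' is exactly 1 between 1.5 and 95 Hz (so < 1 dB ripple over 2-90 Hz) and
#' exactly 0 at and below 0.5 Hz and at and above 105 Hz.  The input is
#' mirror-extended before the FFT, so a constant (DC) input maps to a zero
#' output without edge transients.
#'
#' @param x numeric vector or matrix (columns are channels).
#' @param fs sampling rate in Hz; must exceed `2 * high`.
#' @param low,high band edges in Hz (defaults 1 and 100, the acquisition
#'   filter settings).
#' @param trans_low,trans_high full transition-band widths in Hz around the
#'   low and high edges.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 1, high = 100,
                            trans_low = 1, trans_high = 10) {
  if (fs <= 2 * high) {
    stop("sampling rate must exceed twice the upper band edge (fs > ",
         2 * high, ")")
  }
  if (low <= trans_low / 2) stop("low edge must exceed half the transition width")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  # reflect-extend to an FFT-friendly length, then mirror: the period-2n'
  # extension is continuous everywhere (including the wrap-around), so
  # band-limiting it introduces no edge discontinuity
  np <- stats::nextn(n, c(2, 3, 5))
  ext <- c(seq_len(n), rev(seq_len(n))[seq_len(np - n)])
  ext <- c(ext, rev(ext))
  m <- 2L * np
  f <- (seq_len(m) - 1) / m * fs
  fr <- pmin(f, fs - f)     # fold to [0, fs/2]
  H <- band_mask(fr, low, high, trans_low, trans_high)
  nc <- ncol(xm)
  y <- matrix(0, n, nc)
  for (j in seq(1, nc, by = 2)) {
    # filter two real channels per complex FFT; the mask is real and even,
    # so real and imaginary parts stay separated
    z <- if (j + 1 <= nc) complex(real = xm[ext, j], imaginary = xm[ext, j + 1])
         else complex(real = xm[ext, j], imaginary = 0)
    zf <- stats::fft(stats::fft(z) * H, inverse = TRUE) / m
    y[, j] <- Re(zf)[seq_len(n)]
    if (j + 1 <= nc) y[, j + 1] <- Im(zf)[seq_len(n)]
  }
  colnames(y) <- colnames(xm)
  if (vec) drop(y) else y
}

# raised-cosine band mask: 0 outside, 1 inside, half-cosine transitions
band_mask <- function(f, low, high, trans_low, trans_high) {
  lo0 <- low - trans_low / 2; lo1 <- low + trans_low / 2
  hi0 <- high - trans_high / 2; hi1 <- high + trans_high / 2
  H <- numeric(length(f))
  H[f >= lo1 & f <= hi0] <- 1
  ramp <- f > lo0 & f < lo1
  H[ramp] <- 0.5 * (1 - cos(pi * (f[ramp] - lo0) / trans_low))
  ramp <- f > hi0 & f < hi1
  H[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - hi0) / trans_high))
  H
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive windows of `epoch_len` seconds starting at t = 0; with
#' `overlap = 0` (the default) the windows are non-overlapping and any
#' trailing partial window is discarded, so a 60-s record yields 30 2-s
#' epochs.  All channels are cut with the same windows so spectra and
#' coherences are computed on identical segments.
#'
#' @param rec a `multisite_recording`.
#' @param epoch_len epoch length in seconds (default 2, for 0.5 Hz
#'   resolution).
#' @param overlap fractional overlap between consecutive epochs in
#'   `[0, 1)`; default 0.
#' @return An object of class `epoch_set`: samples as an array
#'   (sample x epoch x channel), keep flags and a rejection log.
#' @export
epoch_signal <- function(rec, epoch_len = 2, overlap = 0) {
  stopifnot(inherits(rec, "multisite_recording"))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  nper <- round(epoch_len * rec$fs)
  if (nper != epoch_len * rec$fs) {
    stop("fs x epoch length must be an integer number of samples")
  }
  n <- nrow(rec$samples)
  if (n < nper) {
    stop("record (", signif(n / rec$fs, 4), " s) is shorter than one epoch (",
         epoch_len, " s): no epochs")
  }
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq.int(1L, n - nper + 1L, by = step)
  ne <- length(starts)
  ep <- array(0, dim = c(nper, ne, 4L),
              dimnames = list(NULL, NULL, theta_regions()))
  for (k in seq_len(ne)) {
    ep[, k, ] <- rec$samples[starts[k]:(starts[k] + nper - 1L), ]
  }
  structure(list(epochs = ep, fs = rec$fs, epoch_len = epoch_len,
                 channel_labels = theta_regions(), meta = rec$meta,
                 cache = new.env(parent = emptyenv()),
                 keep = rep(TRUE, ne),
                 rejection = data.frame(epoch = integer(), channel = character(),
                                        reason = character())),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$epochs)[2], " epochs of ", x$epoch_len,
      " s x 4 channels (", sum(x$keep), " kept)\n", sep = "")
  invisible(x)
}

#' Automatic amplitude-based artifact rejection
#'
#' Drops an epoch when its peak absolute amplitude on any channel exceeds
#' `z_threshold` times that channel's robust scale, the median absolute
#' deviation (scaled by 1.4826) of the whole recording.  Every drop is
#' logged with its reason; rejecting all epochs is an error, never a silent
#' empty result.
#'
#' @param es an `epoch_set`.
#' @param z_threshold threshold in robust-SD units (default 6; `Inf`
#'   disables rejection).
#' @return The `epoch_set` with updated `keep` flags and rejection log.
#' @export
reject_artifacts <- function(es, z_threshold = 6) {
  stopifnot(inherits(es, "epoch_set"))
  ne <- dim(es$epochs)[2]
  if (ne < 1) stop("no epochs to screen")
  logs <- list()
  for (ch in seq_len(4)) {
    all_samp <- as.vector(es$epochs[, , ch])
    # the robust scale stabilises long before the full record length;
    # estimate it from at most ~16k evenly spaced samples
    stride <- max(1L, length(all_samp) %/% 16384L)
    sub <- all_samp[seq.int(1L, length(all_samp), by = stride)]
    scale <- stats::mad(sub, center = stats::median(sub))
    if (scale <= 0) next
    peaks <- apply(abs(es$epochs[, , ch]), 2, max)
    bad <- which(peaks > z_threshold * scale)
    if (length(bad)) {
      es$keep[bad] <- FALSE
      logs[[length(logs) + 1L]] <- data.frame(
        epoch = bad, channel = theta_regions()[ch],
        reason = sprintf("peak amplitude %.3g > %g x robust scale %.3g",
                         peaks[bad], z_threshold, scale))
    }
  }
  if (length(logs)) es$rejection <- rbind(es$rejection, do.call(rbind, logs))
  if (!any(es$keep)) {
    stop("all ", ne, " epochs rejected by the amplitude rule; ",
         "inspect the recording or raise z_threshold")
  }
  es
}

# DFT of every kept epoch, restricted to the 4-12 Hz / 0.5 Hz grid.
# Returns a complex array bin x epoch x channel.  Scaling is such that
# abs(.)^2 for a unit-amplitude on-grid sinusoid equals 0.5 (its mean
# square) under the rectangular taper.
epoch_dft <- function(es, taper = c("rect", "hann")) {
  taper <- match.arg(taper)
  key <- paste(taper, paste(which(es$keep), collapse = ","))
  if (!is.null(es$cache) && !is.null(es$cache[[key]])) {
    return(es$cache[[key]])
  }
  nper <- dim(es$epochs)[1]
  kept <- which(es$keep)
  if (!length(kept)) stop("no kept epochs")
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1)) / nper)
       else rep(1, nper)
  bins <- round(theta_grid() * es$epoch_len)  # DFT bin indices (0-based)
  out <- array(0i, dim = c(length(bins), length(kept), 4L))
  cg <- sum(w)  # coherent gain: preserves narrowband amplitude
  ip <- bins + 1L              # positive-frequency index
  im <- nper - bins + 1L       # conjugate index, for channel unpacking
  for (pr in list(c(1L, 2L), c(3L, 4L))) {
    # two real channels per complex FFT, separated via Hermitian symmetry
    seg <- (es$epochs[, kept, pr[1], drop = FALSE] +
              1i * es$epochs[, kept, pr[2], drop = FALSE])[, , 1] * w
    Z <- stats::mvfft(as.matrix(seg))
    Zp <- Z[ip, , drop = FALSE]
    Zm <- Conj(Z[im, , drop = FALSE])
    out[, , pr[1]] <- (Zp + Zm) / 2 * sqrt(2) / cg
    out[, , pr[2]] <- (Zp - Zm) / (2i) * sqrt(2) / cg
  }
  if (!is.null(es$cache)) es$cache[[key]] <- out
  out
}

#' Absolute power on the 4-12 Hz grid
#'
#' Per-epoch discrete-Fourier periodogram of each kept 2-s epoch, retaining
#' the bins at exact multiples of 0.5 Hz between 4 and 12 Hz, averaged over
#' epochs.  The scaling convention is that a unit-amplitude on-grid
#' sinusoid contributes its mean-square power (0.5) in a single bin;
#' absolute units are arbitrary throughout.
#'
#' @param es an `epoch_set` (after any artifact rejection).
#' @param taper `"rect"` (default, matching plain FFT of 2-s samples) or
#'   `"hann"`.
#' @return An object of class `power_spectrum` with fields `freqs` (17
#'   bins), `ap` (17 x 4 matrix), `n_epochs`, `taper`, `meta`.
#' @export
absolute_power <- function(es, taper = c("rect", "hann")) {
  taper <- match.arg(taper)
  X <- epoch_dft(es, taper)
  ap <- apply(abs(X)^2, c(1, 3), mean)
  dimnames(ap) <- list(NULL, theta_regions())
  structure(list(freqs = theta_grid(), ap = ap, n_epochs = dim(X)[2],
                 taper = taper, meta = es$meta),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat("<power_spectrum> 17 bins (4-12 Hz) x 4 channels, mean of ",
      x$n_epochs, " epochs (", x$taper, " taper)\n", sep = "")
  invisible(x)
}

#' Relative power (percent of the 4-12 Hz band)
#'
#' Per channel, each bin's absolute power expressed as a percentage of the
#' total 4-12 Hz band power, so values sum to exactly 100 per channel.
#'
#' @param ps a `power_spectrum`.
#' @return An object of class `relative_power` with fields `freqs` and
#'   `rp` (17 x 4 matrix of percentages).
#' @export
relative_power <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  tot <- colSums(ps$ap)
  if (any(tot <= 0)) {
    stop("zero total 4-12 Hz power in channel ",
         theta_regions()[which(tot <= 0)[1]], ": relative power undefined")
  }
  rp <- sweep(ps$ap, 2, tot, "/") * 100
  structure(list(freqs = ps$freqs, rp = rp, n_epochs = ps$n_epochs,
                 meta = ps$meta),
            class = "relative_power")
}

#' Natural log of absolute power
#'
#' Elementwise natural logarithm of the absolute-power table.  Bins with
#' non-positive power are returned as `NA` and flagged in the
#' `"excluded"` attribute rather than raising an error.
#'
#' @param ps a `power_spectrum`.
#' @return 17 x 4 matrix of `log(ap)` with an `"excluded"` attribute
#'   (logical matrix of flagged bins).
#' @export
log_absolute_power <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  bad <- ps$ap <= 0
  out <- ps$ap
  out[bad] <- NA_real_
  out[!bad] <- log(out[!bad])
  attr(out, "excluded") <- bad
  out
}

#' Theta peak frequency
#'
#' The grid frequency at which relative power is maximal within a search
#' band (default 5-10 Hz, the band used for all day-by-frequency
#' comparisons).  Ties are resolved toward the lowest frequency.  Daily
#' values are conventionally the mean of the four trial peaks
#' (see [daily_peak_frequency()]).
#'
#' @param rp a `relative_power` (or `power_spectrum`; peak location is the
#'   same since the normalisation is per channel).
#' @param band numeric length 2, inclusive search band in Hz.
#' @return An object of class `peak_summary`: data frame with `channel`,
#'   `peak_freq`, `peak_rp`, plus the band as an attribute.
#' @export
peak_frequency <- function(rp, band = c(5, 10)) {
  vals <- if (inherits(rp, "relative_power")) rp$rp
          else if (inherits(rp, "power_spectrum")) relative_power(rp)$rp
          else stop("rp must be a relative_power or power_spectrum")
  freqs <- theta_grid()
  if (band[1] < freqs[1] || band[2] > freqs[length(freqs)]) {
    stop("band must lie within the 4-12 Hz grid")
  }
  sel <- which(freqs >= band[1] & freqs <= band[2])
  out <- data.frame(channel = theta_regions(),
                    peak_freq = NA_real_, peak_rp = NA_real_)
  for (ch in seq_len(4)) {
    i <- sel[which.max(vals[sel, ch])]   # which.max takes the first maximum
    out$peak_freq[ch] <- freqs[i]
    out$peak_rp[ch] <- vals[i, ch]
  }
  structure(out, band = band, class = c("peak_summary", "data.frame"))
}
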