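#' @export
plot.power_spectrum <- function(x, channels = theta_regions(),
                                log = FALSE, ...) {
  vals <- if (log) {
    v <- log_absolute_power(x)
    attr(v, "excluded") <- NULL
    v
  } else x$ap
  sel <- match(channels, theta_regions())
  graphics::matplot(x$freqs, vals[, sel, drop = FALSE], type = "b",
                    pch = seq_along(sel), lty = 1,
                    xlab = "frequency (Hz)",
                    ylab = if (log) "nl(AP)" else "absolute power (a.u.)",
                    ...)
  graphics::legend("topright", legend = channels, pch = seq_along(sel),
                   col = seq_along(sel), bty = "n")
  invisible(x)
}

#' @export
plot.relative_power <- function(x, channels = theta_regions(), ...) {
  sel <- match(channels, theta_regions())
  graphics::matplot(x$freqs, x$rp[, sel, drop = FALSE], type = "b",
                    pch = seq_along(sel), lty = 1,
                    xlab = "frequency (Hz)", ylab = "relative power (%)",
                    ...)
  graphics::legend("topright", legend = channels, pch = seq_along(sel),
                   col = seq_along(sel), bty = "n")
  invisible(x)
}

#' @export
plot.coherence_spectrum <- function(x, ...) {
  graphics::plot(x$freqs, x$msc, type = "b", ylim = c(0, 1),
                 xlab = "frequency (Hz)", ylab = "magnitude-squared coherence",
                 main = pair_label(x$pair), ...)
  invisible(x)
}

#' @export
plot.swim_trajectory <- function(x, ...) {
  r <- x$pool$radius
  graphics::plot(NA, xlim = c(-r, r), ylim = c(-r, r), asp = 1,
                 xlab = "x (m)", ylab = "y (m)", ...)
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(r * cos(th), r * sin(th))
  if (!isTRUE(x$meta$probe)) {
    pc <- x$pool$platform_center
    graphics::lines(pc[1] + x$pool$platform_radius * cos(th),
                    pc[2] + x$pool$platform_radius * sin(th), lty = 2)
  }
  graphics::lines(x$x, x$y, col = "steelblue")
  graphics::points(x$x[1], x$y[1], pch = 16)
  invisible(x)
}
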