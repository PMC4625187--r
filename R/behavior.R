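#' Circular pool geometry
#'
#' The Morris water-maze pool: a circle of radius 0.75 m (1.5 m diameter)
#' centred at the origin, with a submerged escape platform of 4.5 cm radius
#' (9 cm diameter), by default centred in the north quadrant at half the
#' pool radius.  Quadrants are the 90-degree sectors whose bisectors point
#' north, east, south and west.
#'
#' @param radius pool radius in metres.
#' @param platform_center numeric length 2, platform centre (x, y) in
#'   metres.
#' @param platform_radius platform radius in metres.
#' @return An object of class `pool_geometry`.
#' @export
pool_geometry <- function(radius = 0.75, platform_center = c(0, 0.375),
                          platform_radius = 0.045) {
  if (sqrt(sum(platform_center^2)) + platform_radius > radius) {
    stop("platform must lie entirely inside the pool")
  }
  structure(list(radius = radius, platform_center = platform_center,
                 platform_radius = platform_radius,
                 quadrant_labels = c("N", "S", "E", "W")),
            class = "pool_geometry")
}

#' Swim trajectory
#'
#' A timestamped planar path inside a circular pool.  Timestamps must be
#' strictly increasing and every point must lie inside the pool
#' (x^2 + y^2 <= radius^2, to within floating-point tolerance).
#'
#' @param t,x,y numeric vectors: time (s) and position (m).
#' @param pool a `pool_geometry`.
#' @param meta list: `subject`, `group`, `day`, `trial`, `probe` flag.
#' @return An object of class `swim_trajectory`.
#' @export
swim_trajectory <- function(t, x, y, pool = pool_geometry(), meta = list()) {
  if (length(t) != length(x) || length(x) != length(y)) {
    stop("t, x, y must have equal length")
  }
  if (any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing (row ",
         which(diff(t) <= 0)[1] + 1, ")")
  }
  r2 <- x^2 + y^2
  if (any(r2 > pool$radius^2 * (1 + 1e-9))) {
    stop("trajectory exits the pool at row ",
         which(r2 > pool$radius^2 * (1 + 1e-9))[1])
  }
  if (is.null(meta$probe)) meta$probe <- FALSE
  structure(list(t = t, x = x, y = y, pool = pool, meta = meta),
            class = "swim_trajectory")
}

#' @export
print.swim_trajectory <- function(x, ...) {
  cat("<swim_trajectory> ", length(x$t), " points over ",
      signif(max(x$t) - min(x$t), 4), " s",
      if (isTRUE(x$meta$probe)) " (probe)", "\n", sep = "")
  invisible(x)
}

#' Path length of a trajectory
#'
#' Sum of Euclidean segment lengths between consecutive points.
#'
#' @param traj a `swim_trajectory` (>= 2 points).
#' @return Length in metres.
#' @export
path_length <- function(traj) {
  stopifnot(inherits(traj, "swim_trajectory"))
  if (length(traj$t) < 2) stop("degenerate trajectory: need >= 2 points")
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Escape latency and per-trial swim metrics
#'
#' The latency is the time of the first point inside the platform disc;
#' if the path never enters the platform the trial is a timeout: latency
#' is the trial limit (60 s) and the `guided` flag is set (the animal was
#' guided to the platform).  Path length and mean velocity are computed up
#' to the platform entry (or the whole path for timeouts); mean velocity is
#' path length divided by latency.
#'
#' @param traj a `swim_trajectory` with a platform (not a probe trial).
#' @param max_duration trial limit in seconds (default 60).
#' @return An object of class `trial_metrics`: `latency` (s),
#'   `path_length` (m), `mean_velocity` (m/s), `guided` flag.
#' @export
escape_latency <- function(traj, max_duration = 60) {
  stopifnot(inherits(traj, "swim_trajectory"))
  if (isTRUE(traj$meta$probe)) {
    stop("mode error: probe trajectories have no platform; ",
         "use quadrant_distances()")
  }
  pool <- traj$pool
  d2 <- (traj$x - pool$platform_center[1])^2 +
        (traj$y - pool$platform_center[2])^2
  hit <- which(d2 <= pool$platform_radius^2)
  if (length(hit)) {
    i <- hit[1]
    # detection cannot precede one sample interval
    latency <- if (traj$t[i] > traj$t[1]) traj$t[i] - traj$t[1]
               else traj$t[2] - traj$t[1]
    i <- max(i, 2L)
    pl <- sum(sqrt(diff(traj$x[1:i])^2 + diff(traj$y[1:i])^2))
    guided <- FALSE
  } else {
    latency <- max_duration
    pl <- path_length(traj)
    guided <- TRUE
  }
  structure(list(latency = latency, path_length = pl,
                 mean_velocity = pl / latency, guided = guided),
            class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf("<trial_metrics> latency %.2f s%s, path %.3f m, velocity %.3f m/s\n",
              x$latency, if (x$guided) " (timeout, guided)" else "",
              x$path_length, x$mean_velocity))
  invisible(x)
}

#' Quadrant containing a point
#'
#' Quadrants are 90-degree angular sectors whose bisectors point N, E, S
#' and W; the boundaries lie at 45, 135, 225 and 315 degrees from east.
#' A point exactly on a boundary is assigned to the counterclockwise
#' sector, so (0.3, 0.3) on the 45-degree boundary is "N".
#'
#' @param x,y numeric coordinates (vectorised); must lie inside the pool.
#' @param pool a `pool_geometry`.
#' @return Character vector of quadrant labels.
#' @export
quadrant_of <- function(x, y, pool = pool_geometry()) {
  r2 <- x^2 + y^2
  if (any(r2 > pool$radius^2 * (1 + 1e-9))) {
    stop("point outside the pool")
  }
  ang <- atan2(y, x) * 180 / pi
  ang <- ang %% 360
  ifelse(ang >= 45 & ang < 135, "N",
         ifelse(ang >= 135 & ang < 225, "W",
                ifelse(ang >= 225 & ang < 315, "S", "E")))
}

#' Distance swum in each quadrant
#'
#' Each segment's length is assigned to the quadrant containing its
#' midpoint, so the per-quadrant distances sum exactly to the total path
#' length.
#'
#' @param traj a `swim_trajectory` (>= 2 points).
#' @return An object of class `quadrant_distances`: named distances
#'   (`N`, `S`, `E`, `W`) in metres and `total`.
#' @export
quadrant_distances <- function(traj) {
  stopifnot(inherits(traj, "swim_trajectory"))
  if (length(traj$t) < 2) stop("degenerate trajectory: need >= 2 points")
  seg <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  mx <- (traj$x[-1] + traj$x[-length(traj$x)]) / 2
  my <- (traj$y[-1] + traj$y[-length(traj$y)]) / 2
  # a midpoint of a chord of the pool is always inside the pool
  q <- quadrant_of(mx, my, traj$pool)
  d <- vapply(c("N", "S", "E", "W"), function(l) sum(seg[q == l]), 0)
  structure(list(distances = d, total = sum(seg)),
            class = "quadrant_distances")
}

#' @export
print.quadrant_distances <- function(x, ...) {
  cat("<quadrant_distances> ",
      paste(sprintf("%s=%.3f", names(x$distances), x$distances),
            collapse = " "),
      sprintf(" (total %.3f m)\n", x$total), sep = "")
  invisible(x)
}

#' Write / read a swim trajectory as a delimited text table
#'
#' Tab-separated `(t, x, y)` table with a commented metadata header,
#' mirroring [write_recording()].
#'
#' @param traj a `swim_trajectory`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   a `swim_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(traj$meta)) {
    writeLines(sprintf("#%s\t%s", k, format(traj$meta[[k]])), con)
  }
  writeLines(sprintf("#pool\t%.17g\t%.17g\t%.17g\t%.17g",
                     traj$pool$radius, traj$pool$platform_center[1],
                     traj$pool$platform_center[2],
                     traj$pool$platform_radius), con)
  writeLines("t\tx\ty", con)
  writeLines(sprintf("%.17g\t%.17g\t%.17g", traj$t, traj$x, traj$y), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list(); pool <- pool_geometry()
  for (h in lines[hdr]) {
    kv <- strsplit(sub("^#", "", h), "\t")[[1]]
    if (kv[1] == "pool") {
      v <- as.numeric(kv[-1])
      pool <- pool_geometry(v[1], c(v[2], v[3]), v[4])
    } else meta[[kv[1]]] <- kv[2]
  }
  if (!is.null(meta$probe)) meta$probe <- as.logical(meta$probe)
  if (!is.null(meta$day)) meta$day <- as.integer(meta$day)
  if (!is.null(meta$trial)) meta$trial <- as.integer(meta$trial)
  body <- lines[!hdr]
  dat <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = c("t", "x", "y"),
                           colClasses = "numeric")
  swim_trajectory(dat$t, dat$x, dat$y, pool = pool, meta = meta)
}
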