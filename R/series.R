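#' Construct a trunk kinematics series
#'
#' A kinematics series holds the trunk angular velocity and angular
#' acceleration coordinates about the transverse (pitch) axis, `omega_y`
#' (rad/s) and `alpha_y` (rad/s^2), on a uniform time grid. All detection and
#' classification routines in this package operate on this container.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing on
#'   a uniform grid.
#' @param omega_y Angular velocity about the transverse axis, rad/s.
#' @param alpha_y Angular acceleration about the transverse axis, rad/s^2.
#' @return A data frame of class `kinematics_series` with columns `t`,
#'   `omega_y`, `alpha_y` and attribute `dt` (grid spacing, seconds).
#' @examples
#' ks <- kinematics_series(seq(0, 1, by = 0.01),
#'                         sin(2 * pi * seq(0, 1, by = 0.01)),
#'                         cos(2 * pi * seq(0, 1, by = 0.01)))
#' sampling_interval(ks)
#' @export
kinematics_series <- function(t, omega_y, alpha_y) {
  if (length(t) < 2L)
    stop("a kinematics series needs at least two samples", call. = FALSE)
  if (length(omega_y) != length(t) || length(alpha_y) != length(t))
    stop("t, omega_y and alpha_y must have equal length", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(omega_y)) || !all(is.finite(alpha_y)))
    stop("kinematics series values must be finite", call. = FALSE)
  dt <- check_uniform_grid(t)
  out <- data.frame(t = t, omega_y = omega_y, alpha_y = alpha_y)
  attr(out, "dt") <- dt
  class(out) <- c("kinematics_series", "data.frame")
  out
}

#' @rdname kinematics_series
#' @param x A `kinematics_series`.
#' @export
sampling_interval <- function(x) {
  dt <- attr(x, "dt")
  if (is.null(dt)) dt <- check_uniform_grid(x$t)
  dt
}

# Uniform-grid check: spacing must agree with the median spacing to within a
# relative tolerance (protects against silently differencing ragged series).
check_uniform_grid <- function(t, rel_tol = 1e-6) {
  dt <- diff(t)
  if (any(dt <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  dt0 <- stats::median(dt)
  bad <- which(abs(dt - dt0) > rel_tol * dt0)
  if (length(bad) > 0L)
    stop(sprintf("non-uniform time grid: spacing deviates at row %d (dt = %g, expected %g)",
                 bad[1L] + 1L, dt[bad[1L]], dt0), call. = FALSE)
  dt0
}

#' @export
print.kinematics_series <- function(x, ...) {
  cat(sprintf("<kinematics_series> %d samples, dt = %g s (%.4g Hz), duration %.3f s\n",
              nrow(x), sampling_interval(x), 1 / sampling_interval(x),
              x$t[nrow(x)] - x$t[1L]))
  invisible(x)
}

#' Extract a sub-series by time interval
#'
#' @param x A `kinematics_series`.
#' @param from,to Interval bounds in seconds (inclusive); clamped to the record.
#' @return A `kinematics_series` restricted to `[from, to]`.
#' @export
window_series <- function(x, from, to) {
  keep <- x$t >= from - 1e-12 & x$t <= to + 1e-12
  if (sum(keep) < 2L)
    stop("requested interval contains fewer than two samples", call. = FALSE)
  kinematics_series(x$t[keep], x$omega_y[keep], x$alpha_y[keep])
}

#' Read and write kinematics CSV files
#'
#' The on-disk format is a plain CSV with columns `t`, `omega_y`, `alpha_y`
#' (SI units). Columns are matched by name, so column order is free.
#'
#' @param path Path to a CSV file.
#' @return `read_kinematics_csv` returns a [kinematics_series];
#'   `write_kinematics_csv` returns `path` invisibly.
#' @export
read_kinematics_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("t", "omega_y", "alpha_y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("kinematics CSV '%s' lacks column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  kinematics_series(df$t, df$omega_y, df$alpha_y)
}

#' @rdname read_kinematics_csv
#' @param x A `kinematics_series`.
#' @export
write_kinematics_csv <- function(x, path) {
  df <- as.data.frame(x)[, c("t", "omega_y", "alpha_y")]
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
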