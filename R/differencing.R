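#' Single-sensor numerical differentiation baselines
#'
#' When only one gyroscope is available, the angular acceleration must be
#' obtained by numerically differentiating the angular velocity, which
#' amplifies sensor noise. Two classical difference quotients are provided
#' as baselines against the direct cluster solve.
#'
#' `central_difference` returns `(f[i+1] - f[i-1]) / (2 dt)` at interior
#' points; both boundary samples are `NA` (dropped from downstream extrema
#' analysis rather than padded, to avoid synthetic edge extrema). For white
#' noise of variance `s^2` the output noise variance is `s^2 / (2 dt^2)`.
#'
#' `backward_difference` returns `(f[i] - f[i-1]) / dt` from the second
#' sample on; the first sample is `NA`. Its white-noise variance is
#' `2 s^2 / dt^2`, four times that of the central quotient.
#'
#' @param f Numeric vector, uniformly sampled signal.
#' @param dt Sampling interval, seconds.
#' @return Numeric vector of the same length as `f`, with unavailable
#'   boundary samples set to `NA`.
#' @examples
#' central_difference(3 * seq(0, 1, 0.1), 0.1)   # constant 3 inside
#' backward_difference(3 * seq(0, 1, 0.1), 0.1)
#' @export
central_difference <- function(f, dt) {
  n <- length(f)
  if (n < 3L)
    stop("central difference needs at least 3 samples", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a positive scalar", call. = FALSE)
  out <- rep(NA_real_, n)
  out[2:(n - 1L)] <- (f[3:n] - f[1:(n - 2L)]) / (2 * dt)
  out
}

#' @rdname central_difference
#' @export
backward_difference <- function(f, dt) {
  n <- length(f)
  if (n < 2L)
    stop("backward difference needs at least 2 samples", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a positive scalar", call. = FALSE)
  c(NA_real_, diff(f) / dt)
}

#' Derive a single-IMU kinematics series by differencing
#'
#' Replaces the directly measured `alpha_y` of a series by the numerical
#' derivative of its (noisy) `omega_y`, emulating what a single IMU can
#' provide. Unavailable boundary samples are trimmed from the series.
#'
#' @param kin A [kinematics_series].
#' @param method `"central"` or `"backward"`.
#' @return A [kinematics_series] whose `alpha_y` is the differenced
#'   `omega_y`.
#' @export
differentiate_series <- function(kin, method = c("central", "backward")) {
  method <- match.arg(method)
  dt <- sampling_interval(kin)
  alpha <- switch(method,
                  central = central_difference(kin$omega_y, dt),
                  backward = backward_difference(kin$omega_y, dt))
  keep <- !is.na(alpha)
  kinematics_series(kin$t[keep], kin$omega_y[keep], alpha[keep])
}

#' Zero-phase low-pass smoothing
#'
#' Optional forward-backward exponential smoothing stage for noisy series
#' (off by default throughout the package). The two-pass structure cancels
#' phase lag; the cutoff is the -3 dB frequency of a single pass.
#'
#' @param f Numeric vector.
#' @param dt Sampling interval, seconds.
#' @param cutoff_hz Cutoff frequency, Hz (default 20).
#' @return Smoothed numeric vector of the same length.
#' @export
lowpass_smooth <- function(f, dt, cutoff_hz = 20) {
  if (cutoff_hz <= 0 || cutoff_hz >= 1 / (2 * dt))
    stop("`cutoff_hz` must lie in (0, Nyquist)", call. = FALSE)
  a <- exp(-2 * pi * cutoff_hz * dt)
  fwd <- as.numeric(stats::filter((1 - a) * f, filter = a, method = "recursive"))
  bwd <- rev(as.numeric(stats::filter((1 - a) * rev(fwd), filter = a,
                                      method = "recursive")))
  bwd
}
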