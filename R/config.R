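#' Framework configuration
#'
#' Collects every tunable constant of the detection framework with its
#' default. Units are SI throughout (seconds, rad/s, rad/s^2).
#'
#' @param sample_rate Nominal sample rate, Hz (used by the generators and
#'   the CLI; analysis functions take the grid from the data).
#' @param detection_ratio Threshold scaling for the necessary condition: an
#'   anomaly is an extremum exceeding `detection_ratio` times the
#'   personalised global extrema (default 1.15). Raising it makes detection
#'   stricter.
#' @param outlier_factor_quartile Fence factor `c` of the quartile outlier
#'   test (default 1.5).
#' @param outlier_factor_max_mean Dominance factor `c` of the max-vs-mean
#'   outlier test (default 1.5).
#' @param monitor_alpha,monitor_omega Distribution-monitor settings per
#'   signal: bin width `h`, histogram `limit` and magnitude `clamp`.
#'   Defaults: 1 / 5 / 2 rad/s^2 for angular acceleration and
#'   0.05 / 0.25 / 0.1 rad/s for angular velocity.
#' @param step_tolerance Relative tolerance for matching inter-maximum
#'   spacing to the step period during calibration and periodicity checks
#'   (default 0.10).
#' @param calibration_max_iter Iteration cap of the relevant-maxima
#'   selection (default 20).
#' @param minima_iterations Fixed number of cutoff-raising iterations for
#'   local minima during calibration (default 2; minima are unrelated to
#'   periodic gait events, so no spacing criterion applies).
#' @param step2_offset Extension of the observation window for the
#'   frequency-content analysis, seconds (default 1.25).
#' @param correlation_interval Half-width of the centred interval used to
#'   declare angular-velocity and angular-acceleration outliers
#'   time-correlated, seconds (default 0.15).
#' @param type_interval_cap Upper limit of the initial interval analysed for
#'   perturbation-type classification, seconds (default 0.25).
#' @param boundary_offset_steps Extension of the window for the step-3
#'   context analysis and for the preceding-task interval, in step periods
#'   (default 4).
#' @param sign_convention `+1` if positive `omega_y` means forward (anterior)
#'   trunk pitch, `-1` for the opposite axis orientation.
#' @param autocorr_max_lag Largest lag scanned when estimating dominant
#'   periods, seconds (default 2.5, comfortably above one slow step period).
#' @param min_baseline_steps Floor on baseline duration, in step periods
#'   (default 10).
#' @param peak_rel_tol Peaks within this fraction of the top autocorrelation
#'   peak are treated as co-dominant; the shortest such lag is taken as the
#'   fundamental period (default 0.75).
#' @return A list of class `nearfall_config`.
#' @export
nearfall_config <- function(sample_rate = 100,
                            detection_ratio = 1.15,
                            outlier_factor_quartile = 1.5,
                            outlier_factor_max_mean = 1.5,
                            monitor_alpha = list(h = 1, limit = 5, clamp = 2),
                            monitor_omega = list(h = 0.05, limit = 0.25, clamp = 0.1),
                            step_tolerance = 0.10,
                            calibration_max_iter = 20,
                            minima_iterations = 2,
                            step2_offset = 1.25,
                            correlation_interval = 0.15,
                            type_interval_cap = 0.25,
                            boundary_offset_steps = 4,
                            sign_convention = 1,
                            autocorr_max_lag = 2.5,
                            min_baseline_steps = 10,
                            peak_rel_tol = 0.75) {
  cfg <- list(sample_rate = sample_rate,
              detection_ratio = detection_ratio,
              outlier_factor_quartile = outlier_factor_quartile,
              outlier_factor_max_mean = outlier_factor_max_mean,
              monitor_alpha = monitor_alpha,
              monitor_omega = monitor_omega,
              step_tolerance = step_tolerance,
              calibration_max_iter = calibration_max_iter,
              minima_iterations = minima_iterations,
              step2_offset = step2_offset,
              correlation_interval = correlation_interval,
              type_interval_cap = type_interval_cap,
              boundary_offset_steps = boundary_offset_steps,
              sign_convention = sign_convention,
              autocorr_max_lag = autocorr_max_lag,
              min_baseline_steps = min_baseline_steps,
              peak_rel_tol = peak_rel_tol)
  stopifnot(cfg$detection_ratio > 0, cfg$step_tolerance > 0,
            cfg$sign_convention %in% c(-1, 1))
  class(cfg) <- c("nearfall_config", "list")
  cfg
}

#' Load or save a configuration as YAML
#'
#' `load_config` reads a YAML file and merges it over the defaults of
#' [nearfall_config], so partial files are valid; `save_config` writes the
#' full configuration. `load_config(save_config(cfg, path))` is the
#' identity.
#'
#' @param path YAML file path.
#' @return `load_config` returns a `nearfall_config`; `save_config` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- nearfall_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L)
    stop(sprintf("unknown configuration field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  merged <- utils::modifyList(unclass(defaults), raw)
  do.call(nearfall_config, merged)
}

#' @rdname load_config
#' @param cfg A `nearfall_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
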