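#' Estimate the step frequency of a gait recording
#'
#' The touchdown of each foot leaves a recurring local maximum in the trunk
#' angular acceleration, so the dominant period of `alpha_y` is one step
#' period. The estimate is the reciprocal of the lag of the leading
#' autocorrelation peak; peaks within `peak_rel_tol` of the top coefficient
#' are treated as co-dominant and the shortest such lag wins, which guards
#' against locking onto a multiple of the fundamental.
#'
#' @param kin A [kinematics_series] of (near-)periodic gait.
#' @param config A [nearfall_config].
#' @return A list: `frequency` (Hz), `period` (s), `steps_per_min`
#'   (`60 * frequency`), and the peak table.
#' @export
estimate_step_frequency <- function(kin, config = nearfall_config()) {
  dt <- sampling_interval(kin)
  max_lag <- min(config$autocorr_max_lag, (nrow(kin) - 2L) * dt)
  ac <- autocorrelation(kin$alpha_y, dt, max_lag)
  peaks <- dominant_periods(ac)
  if (nrow(peaks) == 0L)
    stop("calibration failure: no autocorrelation peak found (aperiodic signal?)",
         call. = FALSE)
  lead <- min(peaks$lag[peaks$r >= config$peak_rel_tol * peaks$r[1L]])
  list(frequency = 1 / lead, period = lead,
       steps_per_min = 60 / lead, peaks = peaks)
}

# Relevant-extrema selection for one signal of one baseline trial.
# Maxima: the exclusion cutoff starts at the distribution-monitor bound and
# is raised by one bin width per iteration until the median spacing of the
# surviving maxima matches the step period within the configured tolerance.
# Minima: the cutoff is raised a fixed number of iterations (their timing is
# unrelated to gait events).
select_relevant_extrema <- function(ex, signal_cfg, step_period, config) {
  c_q <- config$outlier_factor_quartile
  init_max <- tryCatch(
    distribution_monitor(ex$maxima, "maxima", h = signal_cfg$h,
                         limit = signal_cfg$limit, clamp = signal_cfg$clamp,
                         c = c_q),
    error = function(e) NULL)
  init_min <- tryCatch(
    distribution_monitor(ex$minima, "minima", h = signal_cfg$h,
                         limit = signal_cfg$limit, clamp = signal_cfg$clamp,
                         c = c_q),
    error = function(e) NULL)
  # magnitudes below the clamp are attributable to noise or irrelevant
  # trunk motion regardless of the histogram outcome, so the clamp is an
  # unconditional exclusion floor
  cutoff <- max(if (is.null(init_max)) 0 else init_max, signal_cfg$clamp)
  tol <- config$step_tolerance
  converged <- FALSE
  for (iter in 0:config$calibration_max_iter) {
    surv <- ex$maxima[ex$maxima$value > cutoff, , drop = FALSE]
    if (nrow(surv) >= 3L) {
      med <- stats::median(diff(surv$time))
      if (abs(med - step_period) <= tol * step_period) {
        converged <- TRUE
        break
      }
    }
    cutoff <- cutoff + signal_cfg$h
  }
  if (!converged)
    stop(sprintf(paste0("calibration failure: relevant-maxima selection did not ",
                        "converge within %d iterations (last cutoff %.3g, ",
                        "%d surviving maxima)"),
                 config$calibration_max_iter, cutoff, nrow(surv)), call. = FALSE)
  cutoff_min <- max(if (is.null(init_min)) 0 else -init_min, signal_cfg$clamp) +
    config$minima_iterations * signal_cfg$h
  surv_min <- ex$minima[ex$minima$value < -cutoff_min, , drop = FALSE]
  if (nrow(surv_min) == 0L)
    stop("calibration failure: no relevant local minima survived the exclusion",
         call. = FALSE)
  list(maxima = surv, minima = surv_min,
       irr_max = cutoff, irr_min = -cutoff_min)
}

signal_thresholds_one_trial <- function(values, times, signal_cfg,
                                        step_period, config) {
  ex <- local_extrema(values, times)
  sel <- select_relevant_extrema(ex, signal_cfg, step_period, config)
  s <- extrema_summary(sel, require_complete = TRUE)
  c(s, list(irr_max = sel$irr_max, irr_min = sel$irr_min))
}

#' Calibrate personalised thresholds from baseline walking
#'
#' Extracts the per-subject detection thresholds from unperturbed baseline
#' walking trials: the averaged step frequency (autocorrelation of
#' `alpha_y`) and, for each of `omega_y` and `alpha_y`, the global maximum
#' and minimum plus the averaged local maxima and minima of the relevant
#' extrema. Relevance is established per trial by a preliminary
#' distribution-monitor exclusion of low-magnitude clutter followed by the
#' iterative selection that raises the exclusion cutoff until the surviving
#' maxima recur at the step period (see [nearfall_config] for every
#' constant). Thresholds are averaged arithmetically across trials and the
#' calibration is deterministic.
#'
#' @param baselines A [kinematics_series] or a list of them (the study
#'   design uses three baseline trials per subject).
#' @param config A [nearfall_config].
#' @return An object of class `personalised_thresholds`: `step_frequency`
#'   (Hz), `step_period` (s), `steps_per_min`, and per-signal lists
#'   `omega_y` / `alpha_y` with `global_max`, `global_min`, `avg_local_max`,
#'   `avg_local_min`, `irr_max`, `irr_min`; plus `n_trials` and the `config`
#'   echo.
#' @examples
#' prof <- gait_profile(noise_omega = 0, noise_alpha = 0)
#' base <- generate_baseline(prof, duration = 20, seed = 1)
#' th <- calibrate_thresholds(base)
#' th$step_frequency
#' @export
calibrate_thresholds <- function(baselines, config = nearfall_config()) {
  if (inherits(baselines, "kinematics_series")) baselines <- list(baselines)
  if (length(baselines) < 1L)
    stop("calibration needs at least one baseline trial", call. = FALSE)
  per_trial <- lapply(baselines, function(kin) {
    sf <- estimate_step_frequency(kin, config)
    dur <- kin$t[nrow(kin)] - kin$t[1L]
    if (dur < config$min_baseline_steps * sf$period)
      stop(sprintf("baseline trial too short: %.1f s < %d step periods",
                   dur, config$min_baseline_steps), call. = FALSE)
    list(step_frequency = sf$frequency,
         alpha_y = signal_thresholds_one_trial(kin$alpha_y, kin$t,
                                               config$monitor_alpha,
                                               sf$period, config),
         omega_y = signal_thresholds_one_trial(kin$omega_y, kin$t,
                                               config$monitor_omega,
                                               sf$period, config))
  })
  avg_field <- function(signal, field)
    mean(vapply(per_trial, function(x) x[[signal]][[field]], numeric(1)))
  fields <- c("global_max", "global_min", "avg_local_max", "avg_local_min",
              "irr_max", "irr_min")
  th <- list(step_frequency = mean(vapply(per_trial, `[[`, numeric(1),
                                          "step_frequency")))
  th$step_period <- 1 / th$step_frequency
  th$steps_per_min <- 60 * th$step_frequency
  for (sig in c("omega_y", "alpha_y"))
    th[[sig]] <- stats::setNames(lapply(fields, function(f) avg_field(sig, f)),
                                 fields)
  th$n_trials <- length(baselines)
  th$config <- config
  class(th) <- c("personalised_thresholds", "list")
  validate_thresholds(th)
  th
}

validate_thresholds <- function(th) {
  for (sig in c("omega_y", "alpha_y")) {
    s <- th[[sig]]
    if (!(s$global_max >= s$avg_local_max && s$avg_local_max > 0))
      stop(sprintf("invalid thresholds for %s: need global_max >= avg_local_max > 0",
                   sig), call. = FALSE)
    if (!(s$global_min <= s$avg_local_min && s$avg_local_min < 0))
      stop(sprintf("invalid thresholds for %s: need global_min <= avg_local_min < 0",
                   sig), call. = FALSE)
  }
  if (th$step_frequency <= 0)
    stop("invalid thresholds: step frequency must be positive", call. = FALSE)
  invisible(th)
}

#' @export
print.personalised_thresholds <- function(x, ...) {
  cat(sprintf("<personalised_thresholds> %d trial(s), cadence %.1f steps/min (%.3f Hz)\n",
              x$n_trials, x$steps_per_min, x$step_frequency))
  for (sig in c("omega_y", "alpha_y")) {
    s <- x[[sig]]
    cat(sprintf("  %-8s global [%.3g, %.3g], avg local [%.3g, %.3g]\n",
                sig, s$global_min, s$global_max, s$avg_local_min, s$avg_local_max))
  }
  invisible(x)
}

#' Read and write personalised thresholds as JSON
#'
#' @param th A `personalised_thresholds` object.
#' @param path JSON file path.
#' @return `write_thresholds` returns `path` invisibly; `read_thresholds`
#'   returns the `personalised_thresholds`.
#' @export
write_thresholds <- function(th, path) {
  out <- unclass(th)
  out$config <- unclass(out$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$config <- do.call(nearfall_config, raw$config)
  class(raw) <- c("personalised_thresholds", "list")
  validate_thresholds(raw)
  raw
}
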