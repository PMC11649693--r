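# Extrema of one signal restricted to a time interval (computed on the full
# series so the segmentation is unaffected by window cropping).
extrema_between <- function(ex, from, to) {
  list(maxima = ex$maxima[ex$maxima$time >= from & ex$maxima$time <= to, ,
                          drop = FALSE],
       minima = ex$minima[ex$minima$time >= from & ex$minima$time <= to, ,
                          drop = FALSE])
}

# Drop extrema whose magnitude falls below the calibrated irrelevance
# bounds (noise clutter would dilute the outlier reference mean). When
# fewer than two relevant extrema remain the unfiltered set is kept: in a
# low-motion context (e.g. quiet stance) the clutter extrema themselves are
# the reference against which a lone transient stands out.
relevant_extrema <- function(ex, sig_th) {
  mx <- ex$maxima[ex$maxima$value > sig_th$irr_max, , drop = FALSE]
  mn <- ex$minima[ex$minima$value < sig_th$irr_min, , drop = FALSE]
  list(maxima = if (nrow(mx) >= 2L) mx else ex$maxima,
       minima = if (nrow(mn) >= 2L) mn else ex$minima)
}

# Max-vs-mean outliers of an interval's extrema, maxima and minima tested
# separately; returns a vector of outlier times (possibly empty).
interval_outlier_times <- function(ex_iv, c) {
  out <- numeric(0)
  for (set in list(ex_iv$maxima, ex_iv$minima)) {
    if (nrow(set) >= 2L) {
      o <- outlier_max_vs_mean(set$value, set$time, c = c)
      if (o$is_outlier) out <- c(out, o$time)
    }
  }
  out
}

# Time-correlated outlier pair: an omega outlier and an alpha outlier within
# a common centred interval of +-corr half-width.
correlated_outlier_pair <- function(ex_w_iv, ex_a_iv, c, corr) {
  tw <- interval_outlier_times(ex_w_iv, c)
  ta <- interval_outlier_times(ex_a_iv, c)
  if (length(tw) == 0L || length(ta) == 0L) return(NULL)
  d <- abs(outer(ta, tw, "-"))
  hit <- which(d <= corr, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  list(alpha_time = ta[hit[1L, 1L]], omega_time = tw[hit[1L, 2L]])
}

# Touchdown-type (dominant) alpha maxima of an interval: maxima reaching at
# least half the interval's largest maximum and clearing the noise clamp.
dominant_maxima <- function(mx, clamp) {
  if (nrow(mx) == 0L) return(mx)
  cutoff <- max(clamp, 0.5 * max(mx$value))
  mx[mx$value >= cutoff, , drop = FALSE]
}

#' Step 1: periodicity versus correlated outliers
#'
#' First sufficient-condition check on an observation window. A sustained
#' train of touchdown-type `alpha_y` maxima (at least five) recurring at a
#' stable spacing (three or more successive spacings within the step
#' tolerance of their median) identifies a periodic ADL such as running; a
#' decaying recovery transient cannot supply that many repetitions.
#' Otherwise, a time-correlated pair of max-vs-mean outliers in the
#' relevant extrema of `omega_y` and `alpha_y` (within the configured
#' correlation interval) is the signature of a balance recovery response.
#' Neither pattern leaves the window undecided.
#'
#' @param window An `observation_window`.
#' @param kin The [kinematics_series].
#' @param th Personalised thresholds.
#' @param config A [nearfall_config].
#' @return A list `verdict` (`"recovery"`, `"ADL"` or `"undecided"`) plus
#'   supporting evidence.
#' @export
step1_periodicity_vs_outliers <- function(window, kin, th, config = th$config) {
  if (is.null(config)) config <- nearfall_config()
  ex_w <- extrema_between(local_extrema(kin$omega_y, kin$t),
                          window$onset, window$offset)
  ex_a <- extrema_between(local_extrema(kin$alpha_y, kin$t),
                          window$onset, window$offset)
  # periodicity first: a sustained train of touchdown-type maxima recurring
  # at a stable spacing is an ADL signature; a decaying recovery transient
  # cannot supply enough repetitions
  dom <- dominant_maxima(ex_a$maxima, config$monitor_alpha$clamp)
  if (nrow(dom) >= 5L) {
    sp <- diff(dom$time)
    med <- stats::median(sp)
    consistent <- sum(abs(sp - med) <= config$step_tolerance * med)
    if (consistent >= 3L)
      return(list(verdict = "ADL", condition = "periodic_ADL",
                  evidence = list(spacings = sp, consistent = consistent)))
  }
  pair <- correlated_outlier_pair(relevant_extrema(ex_w, th$omega_y),
                                  relevant_extrema(ex_a, th$alpha_y),
                                  c = config$outlier_factor_max_mean,
                                  corr = config$correlation_interval)
  if (!is.null(pair))
    return(list(verdict = "recovery", condition = "correlated_outliers",
                evidence = pair))
  list(verdict = "undecided", condition = NA_character_, evidence = NULL)
}

# Transient short-lag content of one signal: quartile-outlier peaks of r_k
# whose lag implies a frequency above the step frequency and which are not
# part of a repeated (harmonic-multiple) pattern.
transient_short_lag <- function(values, dt, step_period, config) {
  max_lag <- min(config$autocorr_max_lag, (length(values) - 2L) * dt)
  if (max_lag <= dt) return(FALSE)
  ac <- tryCatch(autocorrelation(values, dt, max_lag), error = function(e) NULL)
  if (is.null(ac)) return(FALSE)
  peaks <- dominant_periods(ac)
  if (nrow(peaks) < 4L) return(FALSE)
  flagged <- peaks[outlier_quartile(peaks$r, c = config$outlier_factor_quartile) &
                     peaks$lag < step_period, , drop = FALSE]
  if (nrow(flagged) == 0L) return(FALSE)
  tol <- config$step_tolerance
  for (L in flagged$lag) {
    mult <- peaks$lag / L
    repeated <- any(abs(mult - round(mult)) <= tol & round(mult) >= 2)
    if (!repeated) return(TRUE)
  }
  FALSE
}

#' Step 2: transient frequency content
#'
#' Second sufficient-condition check, applied when step 1 is undecided. The
#' autocorrelation of both signals over the window extended by the step-2
#' offset (1.25 s) is searched for coefficient peaks flagged by the
#' quartile outlier test whose lag implies a frequency above the step
#' frequency and which do not recur as integer multiples of a base lag — a
#' transient, non-gait frequency component indicating a recovery response.
#'
#' @inheritParams step1_periodicity_vs_outliers
#' @return A list with `verdict` (`"recovery"` or `"undecided"`) and a flag
#'   `truncated` when the extension was clamped to the record.
#' @export
step2_frequency_content <- function(window, kin, th, config = th$config) {
  if (is.null(config)) config <- nearfall_config()
  dt <- sampling_interval(kin)
  from <- window$onset - config$step2_offset
  to <- window$offset + config$step2_offset
  truncated <- from < kin$t[1L] || to > kin$t[nrow(kin)]
  sub <- window_series(kin, max(from, kin$t[1L]), min(to, kin$t[nrow(kin)]))
  for (sig in c("alpha_y", "omega_y")) {
    if (transient_short_lag(sub[[sig]], dt, th$step_period, config))
      return(list(verdict = "recovery", condition = "transient_frequency",
                  evidence = list(signal = sig), truncated = truncated))
  }
  list(verdict = "undecided", condition = NA_character_, evidence = NULL,
       truncated = truncated)
}

#' Step 3: boundary-context outliers
#'
#' Final, deciding check. The window is extended by four step periods
#' before the onset and after the offset, exposing the motion context; a
#' time-correlated max-vs-mean outlier pair in the two signals over this
#' extended interval marks a recovery response, otherwise the window is an
#' ADL.
#'
#' @inheritParams step1_periodicity_vs_outliers
#' @return A list with `verdict` (`"recovery"` or `"ADL"`).
#' @export
step3_boundary_outliers <- function(window, kin, th, config = th$config) {
  if (is.null(config)) config <- nearfall_config()
  off <- config$boundary_offset_steps * th$step_period
  from <- window$onset - off
  to <- window$offset + off
  truncated <- from < kin$t[1L] || to > kin$t[nrow(kin)]
  from <- max(from, kin$t[1L]); to <- min(to, kin$t[nrow(kin)])
  ex_w <- extrema_between(local_extrema(kin$omega_y, kin$t), from, to)
  ex_a <- extrema_between(local_extrema(kin$alpha_y, kin$t), from, to)
  pair <- correlated_outlier_pair(relevant_extrema(ex_w, th$omega_y),
                                  relevant_extrema(ex_a, th$alpha_y),
                                  c = config$outlier_factor_max_mean,
                                  corr = config$correlation_interval)
  if (!is.null(pair))
    return(list(verdict = "recovery", condition = "boundary_outliers",
                evidence = pair, truncated = truncated))
  list(verdict = "ADL", condition = "default_ADL", evidence = NULL,
       truncated = truncated)
}

#' Reference features of the locomotor tasks
#'
#' Builds the per-task reference features (average local maximum of
#' `alpha_y`, rad/s^2, and dominant period, seconds) used to identify the
#' motion preceding a perturbation. The walking reference is the calibrated
#' thresholds themselves; the defaults for running and standing scale the
#' walking reference by configurable factors (running amplitudes about four
#' times walking, cadence about a third higher; standing amplitudes at the
#' noise clamp with no defined period). Measured per-task references can be
#' supplied instead.
#'
#' @param th Personalised thresholds.
#' @param running_amp_factor Running/walking amplitude ratio (default
#'   181/44, the cohort-average global maxima ratio).
#' @param running_cadence_factor Running/walking cadence ratio (default 1.3).
#' @param standing_amp Standing reference amplitude, rad/s^2 (default half
#'   the angular-acceleration noise clamp).
#' @param config A [nearfall_config].
#' @return A list of class `task_reference` with `standing`, `walking`,
#'   `running`, each `list(amp, period)`.
#' @export
task_references <- function(th, running_amp_factor = 181 / 44,
                            running_cadence_factor = 1.3,
                            standing_amp = NULL, config = th$config) {
  if (is.null(config)) config <- nearfall_config()
  if (is.null(standing_amp)) standing_amp <- config$monitor_alpha$clamp / 2
  refs <- list(standing = list(amp = standing_amp, period = NA_real_),
               walking = list(amp = th$alpha_y$avg_local_max,
                              period = th$step_period),
               running = list(amp = th$alpha_y$avg_local_max * running_amp_factor,
                              period = th$step_period / running_cadence_factor))
  class(refs) <- c("task_reference", "list")
  refs
}

# Features of a pre-onset interval: average relevant alpha maximum and
# dominant period; NA period for aperiodic content.
preceding_features <- function(kin, from, to, th, config) {
  sub <- window_series(kin, from, to)
  dt <- sampling_interval(sub)
  ex <- local_extrema(sub$alpha_y, sub$t)
  clamp <- config$monitor_alpha$clamp
  rel <- ex$maxima[ex$maxima$value > clamp, , drop = FALSE]
  period <- tryCatch({
    sf <- estimate_step_frequency(sub, config)
    sf$period
  }, error = function(e) NA_real_)
  # keep the maxima consistent with the interval's own periodicity where
  # possible (same principle as the calibration's relevant-maxima selection)
  if (!is.na(period) && nrow(rel) >= 4L) {
    cutoff <- clamp
    for (iter in 0:config$calibration_max_iter) {
      surv <- ex$maxima[ex$maxima$value > cutoff, , drop = FALSE]
      if (nrow(surv) >= 3L) {
        sp <- diff(surv$time)
        if (all(abs(sp - period) <= config$step_tolerance * period)) {
          rel <- surv
          break
        }
      }
      if (nrow(surv) < 3L) break
      cutoff <- cutoff + config$monitor_alpha$h
    }
  }
  list(amp = if (nrow(rel) > 0L) mean(rel$value) else 0, period = period)
}

#' Identify the locomotor task preceding a perturbation
#'
#' Analyses the interval of four step periods ending immediately before the
#' window onset. If no `alpha_y` maximum clears the noise clamp the
#' preceding task is quiet standing (amplitude floor rule); otherwise the
#' interval's features (average relevant local maximum of `alpha_y`,
#' dominant period) are compared to the task references and the task with
#' the least mean absolute relative deviation wins, ties going to walking.
#'
#' @param kin A [kinematics_series].
#' @param onset Window onset, seconds.
#' @param th Personalised thresholds.
#' @param refs A `task_reference` (default [task_references]).
#' @param config A [nearfall_config].
#' @return A list: `task` (`"standing"`, `"walking"`, `"running"`),
#'   `features`, `deviations`, `truncated`.
#' @export
classify_preceding_task <- function(kin, onset, th, refs = NULL,
                                    config = th$config) {
  if (is.null(config)) config <- nearfall_config()
  if (is.null(refs)) refs <- task_references(th, config = config)
  dt <- sampling_interval(kin)
  span <- config$boundary_offset_steps * th$step_period
  to <- onset - dt
  from <- onset - span
  truncated <- from < kin$t[1L]
  from <- max(from, kin$t[1L])
  if (to - from < 2 * dt)
    return(list(task = "standing", features = NULL, deviations = NULL,
                truncated = TRUE))
  feat <- preceding_features(kin, from, to, th, config)
  if (feat$amp <= config$monitor_alpha$clamp)
    return(list(task = "standing", features = feat, deviations = NULL,
                truncated = truncated))
  devs <- vapply(refs, function(ref) {
    terms <- abs(feat$amp - ref$amp) / ref$amp
    if (!is.na(feat$period) && !is.na(ref$period))
      terms <- c(terms, abs(feat$period - ref$period) / ref$period)
    mean(terms)
  }, numeric(1))
  best <- min(devs)
  task <- names(devs)[devs <= best + 1e-12]
  task <- if ("walking" %in% task) "walking" else task[1L] # ties -> walking
  list(task = task, features = feat, deviations = devs, truncated = truncated)
}

#' Classify the perturbation type of a recovery window
#'
#' Analyses the initial balance response: the dominant (largest-magnitude)
#' `omega_y` extremum inside the initial interval of the window (half the
#' window duration, capped at 0.25 s). Under the configured sign convention
#' (positive `omega_y` = anterior/forward pitch), a positive response during
#' walking is a trip and a negative one a slip; from standing they are an
#' anterior or posterior loss of balance. A running context yields no type
#' (only the direction is reported).
#'
#' @param kin A [kinematics_series].
#' @param window An `observation_window` classified as recovery.
#' @param preceding Preceding task, `"standing"`, `"walking"` or `"running"`.
#' @param th Personalised thresholds.
#' @param config A [nearfall_config].
#' @return A list: `type` (`"trip"`, `"slip"`, `"anterior_loss"`,
#'   `"posterior_loss"` or `"none"`), `direction` (`"anterior"` /
#'   `"posterior"`), and the deciding `extremum`.
#' @export
classify_perturbation_type <- function(kin, window, preceding,
                                       th, config = th$config) {
  if (is.null(config)) config <- nearfall_config()
  dur <- window$offset - window$onset
  to <- window$onset + min(config$type_interval_cap, dur / 2)
  # segment the initial interval itself, so the in-interval peak of an
  # excursion that continues past the interval still counts
  sub <- window_series(kin, window$onset, to)
  ex <- local_extrema(sub$omega_y, sub$t)
  cand <- rbind(ex$maxima, ex$minima)
  dom <- cand[which.max(abs(cand$value)), , drop = FALSE]
  if (dom$value == 0)
    stop("unclassifiable perturbation type: no directed angular-velocity extremum",
         call. = FALSE)
  dir_sign <- sign(dom$value) * config$sign_convention
  direction <- if (dir_sign > 0) "anterior" else "posterior"
  type <- switch(preceding,
                 walking = if (dir_sign > 0) "trip" else "slip",
                 standing = if (dir_sign > 0) "anterior_loss" else "posterior_loss",
                 running = "none")
  list(type = type, direction = direction,
       extremum = list(value = dom$value, time = dom$time))
}

#' Classify every observation window of a trial
#'
#' Composes the full sufficient-condition cascade: windows from
#' [detect_windows] pass through steps 1-3 (short-circuiting: the first
#' terminal verdict stands); recovery windows additionally receive the
#' preceding-task and perturbation-type classification. Pure ADL trials
#' yield an empty list.
#'
#' @param kin A [kinematics_series].
#' @param th Personalised thresholds.
#' @param refs Optional `task_reference` (default [task_references]).
#' @param config A [nearfall_config].
#' @return A list of `perturbation_call` objects, one per window in
#'   temporal order, each with `is_recovery`, `type`, `preceding`,
#'   `direction`, `window`, and a `trace` recording the deciding step and
#'   condition.
#' @export
classify_trial <- function(kin, th, refs = NULL, config = th$config) {
  if (is.null(config)) config <- nearfall_config()
  if (is.null(refs)) refs <- task_references(th, config = config)
  windows <- detect_windows(kin, th, config = config)
  lapply(windows, function(w) {
    res <- step1_periodicity_vs_outliers(w, kin, th, config)
    step <- 1L
    if (res$verdict == "undecided") {
      res <- step2_frequency_content(w, kin, th, config)
      step <- 2L
    }
    if (res$verdict == "undecided") {
      res <- step3_boundary_outliers(w, kin, th, config)
      step <- 3L
    }
    trace <- list(step = step, condition = res$condition, evidence = res$evidence)
    if (res$verdict == "recovery") {
      pre <- classify_preceding_task(kin, w$onset, th, refs, config)
      ty <- tryCatch(
        classify_perturbation_type(kin, w, pre$task, th, config),
        error = function(e) list(type = "none", direction = NA_character_,
                                 extremum = NULL, error = conditionMessage(e)))
      call <- list(is_recovery = TRUE, type = ty$type, preceding = pre$task,
                   direction = ty$direction, window = w, trace = trace)
    } else {
      call <- list(is_recovery = FALSE, type = "none", preceding = NA_character_,
                   direction = NA_character_, window = w, trace = trace)
    }
    class(call) <- "perturbation_call"
    call
  })
}

#' @export
print.perturbation_call <- function(x, ...) {
  cat(sprintf("<perturbation_call> %s%s [%.3f, %.3f] s (step %d: %s)\n",
              if (x$is_recovery) "RECOVERY" else "ADL",
              if (x$is_recovery)
                sprintf(" type=%s preceding=%s", x$type, x$preceding) else "",
              x$window$onset, x$window$offset, x$trace$step, x$trace$condition))
  invisible(x)
}

#' Convert a call list to a data frame
#'
#' @param calls List of `perturbation_call` objects from [classify_trial].
#' @return One row per call: verdict, type, preceding task, direction,
#'   window bounds and the deciding step/condition.
#' @export
calls_to_df <- function(calls) {
  if (length(calls) == 0L)
    return(data.frame(is_recovery = logical(0), type = character(0),
                      preceding = character(0), direction = character(0),
                      onset = numeric(0), offset = numeric(0),
                      step = integer(0), condition = character(0)))
  data.frame(
    is_recovery = vapply(calls, `[[`, logical(1), "is_recovery"),
    type = vapply(calls, `[[`, character(1), "type"),
    preceding = vapply(calls, `[[`, character(1), "preceding"),
    direction = vapply(calls, `[[`, character(1), "direction"),
    onset = vapply(calls, function(x) x$window$onset, numeric(1)),
    offset = vapply(calls, function(x) x$window$offset, numeric(1)),
    step = vapply(calls, function(x) x$trace$step, integer(1)),
    condition = vapply(calls, function(x) x$trace$condition, character(1)))
}
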