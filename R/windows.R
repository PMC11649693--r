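# Zero crossings of a sampled signal under the >=0 sign map: returns the
# indices i such that the sign changes between samples i and i+1.
zero_crossing_index <- function(f) {
  sgn <- ifelse(f >= 0, 1L, -1L)
  which(sgn[-length(sgn)] != sgn[-1L])
}

# Threshold-exceeding extrema of one signal: maxima above ratio * global_max
# and minima below ratio * global_min, merged and sorted by time.
threshold_triggers <- function(ex, sig_th, ratio) {
  up <- ex$maxima[ex$maxima$value > ratio * sig_th$global_max, , drop = FALSE]
  dn <- ex$minima[ex$minima$value < ratio * sig_th$global_min, , drop = FALSE]
  if (nrow(up) > 0L) up$kind <- "max"
  if (nrow(dn) > 0L) dn$kind <- "min"
  out <- rbind(up, dn)
  if (nrow(out) > 0L) out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect observation windows (necessary condition)
#'
#' Flags the time intervals that may contain a balance recovery response.
#' Local extrema of `omega_y` exceeding `ratio` times the personalised
#' global extrema are clustered into temporary windows (clusters split where
#' adjacent anomalies are more than one step period apart; boundary equality
#' keeps the cluster). Each temporary window, extended by half a step period
#' on both sides, is kept only if `alpha_y` also has an extremum beyond
#' `ratio` times its global thresholds inside the extended bounds — the
#' joint-anomaly requirement that separates perturbed locomotion from
#' single-signal events such as object manipulation. Kept windows receive a
#' refined onset ([refine_onset]) and offset ([refine_offset]); overlapping
#' refined windows are merged.
#'
#' @param kin A [kinematics_series].
#' @param th A `personalised_thresholds` from [calibrate_thresholds].
#' @param ratio Threshold scaling of the necessary condition (default from
#'   the configuration, 1.15). Raising it never increases the number of
#'   windows.
#' @param config A [nearfall_config].
#' @return A list of `observation_window` objects, pairwise disjoint and
#'   sorted by onset. Each has fields `onset`, `offset`, `temporary`,
#'   `extended` (two-element bounds), `triggers` (per-signal extrema data
#'   frames), and truncation flags.
#' @export
detect_windows <- function(kin, th, ratio = NULL, config = th$config) {
  if (!inherits(th, "personalised_thresholds"))
    stop("configuration error: calibrated personalised thresholds required",
         call. = FALSE)
  if (is.null(config)) config <- nearfall_config()
  if (is.null(ratio)) ratio <- config$detection_ratio
  per <- th$step_period
  if (kin$t[nrow(kin)] - kin$t[1L] <= per)
    stop("series shorter than one step period", call. = FALSE)
  ex_w <- local_extrema(kin$omega_y, kin$t)
  ex_a <- local_extrema(kin$alpha_y, kin$t)
  trig_w <- threshold_triggers(ex_w, th$omega_y, ratio)
  if (nrow(trig_w) == 0L) return(list())
  trig_a_all <- threshold_triggers(ex_a, th$alpha_y, ratio)
  cluster_id <- cumsum(c(1, diff(trig_w$time) > per))
  windows <- list()
  for (cid in unique(cluster_id)) {
    cl <- trig_w[cluster_id == cid, , drop = FALSE]
    temporary <- c(min(cl$time), max(cl$time))
    extended <- c(temporary[1L] - per / 2, temporary[2L] + per / 2)
    in_ext <- trig_a_all$time >= extended[1L] & trig_a_all$time <= extended[2L]
    if (!any(in_ext)) next
    trig_a <- trig_a_all[in_ext, , drop = FALSE]
    w <- structure(list(onset = NA_real_, offset = NA_real_,
                        temporary = temporary, extended = extended,
                        triggers = list(omega_y = cl, alpha_y = trig_a),
                        truncated_start = FALSE, truncated_end = FALSE),
                   class = "observation_window")
    w <- refine_onset(w, kin)
    w <- refine_offset(w, kin, th, ratio = ratio, config = config)
    windows[[length(windows) + 1L]] <- w
  }
  merge_windows(windows)
}

#' Refine the onset of an observation window
#'
#' The onset is the sample immediately after the last zero crossing of
#' `alpha_y` that precedes the first threshold-exceeding extremum of the
#' temporary window. When no preceding crossing exists the onset is clamped
#' to the series start and the window is flagged truncated.
#'
#' @param window An `observation_window` with triggering extrema.
#' @param kin The [kinematics_series] the window was detected in.
#' @return The window with `onset` (seconds) and `truncated_start` set.
#' @export
refine_onset <- function(window, kin) {
  first_trig <- min(window$triggers$omega_y$time, window$triggers$alpha_y$time)
  zc <- zero_crossing_index(kin$alpha_y)
  after <- kin$t[zc + 1L] # sample immediately after each crossing
  prev <- after[after <= first_trig + 1e-12]
  if (length(prev) == 0L) {
    window$onset <- kin$t[1L]
    window$truncated_start <- TRUE
  } else {
    window$onset <- max(prev)
    window$truncated_start <- FALSE
  }
  window
}

#' Refine the offset of an observation window
#'
#' The candidate offset is the zero crossing of `alpha_y` that follows the
#' last in-window threshold-exceeding extremum. It is accepted only if,
#' for one step period after it, every local extremum of both signals stays
#' within the threshold bandwidths `[ratio * global_min, ratio *
#' global_max]`; a violating extremum re-extends the window to include it
#' and the routine repeats. Reaching the end of the record clamps the
#' offset and flags the window truncated.
#'
#' @inheritParams refine_onset
#' @param th Personalised thresholds.
#' @param ratio Threshold band scaling (default: the detection ratio).
#' @param config A [nearfall_config].
#' @return The window with `offset` and `truncated_end` set.
#' @export
refine_offset <- function(window, kin, th, ratio = NULL, config = th$config) {
  if (is.null(config)) config <- nearfall_config()
  if (is.null(ratio)) ratio <- config$detection_ratio
  per <- th$step_period
  ex_w <- local_extrema(kin$omega_y, kin$t)
  ex_a <- local_extrema(kin$alpha_y, kin$t)
  band_violations <- function(from, to) {
    viol <- numeric(0)
    for (pair in list(list(ex_w, th$omega_y), list(ex_a, th$alpha_y))) {
      ex <- pair[[1L]]; sig <- pair[[2L]]
      up <- ex$maxima[ex$maxima$time > from & ex$maxima$time <= to &
                        ex$maxima$value > ratio * sig$global_max, , drop = FALSE]
      dn <- ex$minima[ex$minima$time > from & ex$minima$time <= to &
                        ex$minima$value < ratio * sig$global_min, , drop = FALSE]
      viol <- c(viol, up$time, dn$time)
    }
    viol
  }
  zc <- zero_crossing_index(kin$alpha_y)
  after <- kin$t[zc + 1L]
  last_ex <- max(window$triggers$omega_y$time, window$triggers$alpha_y$time)
  t_end <- kin$t[nrow(kin)]
  repeat {
    nxt <- after[after > last_ex + 1e-12]
    if (length(nxt) == 0L) {
      window$offset <- t_end
      window$truncated_end <- TRUE
      break
    }
    cand <- min(nxt)
    viol <- band_violations(cand, cand + per)
    if (length(viol) == 0L) {
      window$offset <- cand
      window$truncated_end <- FALSE
      break
    }
    last_ex <- max(viol)
  }
  window
}

# Overlapping refined windows are merged (union of bounds and triggers).
merge_windows <- function(windows) {
  if (length(windows) <= 1L) return(windows)
  windows <- windows[order(vapply(windows, `[[`, numeric(1), "onset"))]
  out <- list(windows[[1L]])
  for (w in windows[-1L]) {
    last <- out[[length(out)]]
    if (w$onset <= last$offset + 1e-12) {
      last$offset <- max(last$offset, w$offset)
      last$temporary <- range(c(last$temporary, w$temporary))
      last$extended <- range(c(last$extended, w$extended))
      last$triggers$omega_y <- rbind(last$triggers$omega_y, w$triggers$omega_y)
      last$triggers$alpha_y <- rbind(last$triggers$alpha_y, w$triggers$alpha_y)
      last$truncated_end <- w$truncated_end
      out[[length(out)]] <- last
    } else {
      out[[length(out) + 1L]] <- w
    }
  }
  out
}

#' @export
print.observation_window <- function(x, ...) {
  cat(sprintf("<observation_window> [%.3f, %.3f] s (%d omega, %d alpha anomalies)%s%s\n",
              x$onset, x$offset, nrow(x$triggers$omega_y), nrow(x$triggers$alpha_y),
              if (x$truncated_start) " [start truncated]" else "",
              if (x$truncated_end) " [end truncated]" else ""))
  invisible(x)
}

#' Convert a window list to a data frame
#'
#' @param windows List of `observation_window` objects.
#' @return A data frame with one row per window.
#' @export
windows_to_df <- function(windows) {
  if (length(windows) == 0L)
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      truncated_start = logical(0), truncated_end = logical(0)))
  data.frame(onset = vapply(windows, `[[`, numeric(1), "onset"),
             offset = vapply(windows, `[[`, numeric(1), "offset"),
             truncated_start = vapply(windows, `[[`, logical(1), "truncated_start"),
             truncated_end = vapply(windows, `[[`, logical(1), "truncated_end"))
}
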