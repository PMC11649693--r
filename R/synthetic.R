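#' Synthetic gait profile
#'
#' Parameters of the synthetic trunk-kinematics generator. The generator
#' emulates the statistical structure the detection framework assumes:
#' quasi-periodic transverse-axis angular velocity built from band-limited
#' harmonics of the step frequency plus a short Gaussian touchdown transient
#' at every step, with the angular acceleration as the exact analytic time
#' derivative, so that the cluster signal, the differenced single-sensor
#' signal and the underlying truth are mutually consistent. Defaults target
#' the walking conditions of the study population: cadence near 117
#' steps/min and touchdown angular-acceleration peaks in the tens of
#' rad/s^2 (cohort averaged local maxima 19-46 rad/s^2, global maxima
#' 28-84 rad/s^2, running about four times walking).
#'
#' @param step_frequency Step frequency, Hz (default 116.8 / 60).
#' @param omega_harmonics Amplitudes (rad/s) of the angular-velocity
#'   harmonics at 1x, 2x, 3x the step frequency.
#' @param pulse_amplitude Target peak of the touchdown angular-acceleration
#'   transient, rad/s^2.
#' @param pulse_width Width (Gaussian sd, seconds) of the touchdown
#'   angular-velocity transient; its analytic derivative is the biphasic
#'   angular-acceleration pulse.
#' @param pulse_jitter Relative step-to-step variability of the touchdown
#'   amplitude (lognormal sd).
#' @param touchdown_phase Phase of the gait cycle (fraction of a step
#'   period) at which the touchdown transient is centred.
#' @param noise_omega,noise_alpha Gaussian measurement noise sd per sample
#'   on `omega_y` (rad/s) and `alpha_y` (rad/s^2). The cluster measures
#'   `alpha_y` directly, so its noise is independent of `noise_omega`.
#' @param noise_accel Accelerometer noise sd (m/s^2) used by
#'   [generate_cluster_trial].
#' @param artefact_prob Probability that a heel strike leaves a short
#'   (about 20 ms) impact artefact in the *measured* angular velocity
#'   (soft-tissue / impact vibration, common-mode across the rigidly
#'   mounted gyroscopes). Artefacts scale with event intensity, are part
#'   of the noise model, and vanish when the noise is switched off. The
#'   accelerometers, and hence the cluster's angular-acceleration solve,
#'   are unaffected; numerical differentiation of the angular velocity
#'   amplifies them by the reciprocal of the sampling interval.
#' @param sample_rate Sample rate, Hz.
#' @return A list of class `gait_profile`.
#' @export
gait_profile <- function(step_frequency = 116.8 / 60,
                         omega_harmonics = c(0.35, 0.12, 0.05),
                         pulse_amplitude = 32,
                         pulse_width = 0.025,
                         pulse_jitter = 0.15,
                         touchdown_phase = 0.25,
                         noise_omega = 0.02,
                         noise_alpha = 0.3,
                         noise_accel = 0.02,
                         artefact_prob = 0.3,
                         sample_rate = 100) {
  stopifnot(step_frequency > 0, pulse_amplitude > 0, pulse_width > 0,
            sample_rate > 0, noise_omega >= 0, noise_alpha >= 0,
            noise_accel >= 0, artefact_prob >= 0, artefact_prob <= 1)
  structure(list(step_frequency = step_frequency,
                 omega_harmonics = omega_harmonics,
                 pulse_amplitude = pulse_amplitude,
                 pulse_width = pulse_width,
                 pulse_jitter = pulse_jitter,
                 touchdown_phase = touchdown_phase,
                 noise_omega = noise_omega,
                 noise_alpha = noise_alpha,
                 noise_accel = noise_accel,
                 artefact_prob = artefact_prob,
                 sample_rate = sample_rate),
            class = "gait_profile")
}

# Gaussian bump train and its analytic derivative.
bump_train <- function(t, centers, amps, sd) {
  if (length(centers) == 0L)
    return(list(value = numeric(length(t)), deriv = numeric(length(t))))
  u <- outer(t, centers, "-")
  g <- exp(-u^2 / (2 * sd^2))
  val <- g %*% amps
  der <- -(g * u / sd^2) %*% amps
  list(value = drop(val), deriv = drop(der))
}

# Raised-cosine on/off envelope over [t_on, t_off] with ramp length r,
# with analytic derivative.
gait_envelope <- function(t, t_on, t_off, r = 0.5) {
  e <- numeric(length(t))
  d <- numeric(length(t))
  up <- t >= t_on & t < t_on + r
  full <- t >= t_on + r & t <= t_off - r
  down <- t > t_off - r & t <= t_off
  e[up] <- 0.5 * (1 - cos(pi * (t[up] - t_on) / r))
  d[up] <- 0.5 * pi / r * sin(pi * (t[up] - t_on) / r)
  e[full] <- 1
  e[down] <- 0.5 * (1 - cos(pi * (t_off - t[down]) / r))
  d[down] <- -0.5 * pi / r * sin(pi * (t_off - t[down]) / r)
  list(value = e, deriv = d)
}

# Per-task generator parameters. Running touchdowns are about four times
# the walking amplitude (cohort averaged global maxima 181 vs 44 rad/s^2)
# and sharper; cadence about a third higher.
task_params <- function(task, profile) {
  base <- list(freq = profile$step_frequency,
               harmonics = profile$omega_harmonics,
               pulse = profile$pulse_amplitude,
               width = profile$pulse_width,
               artefact_amp = 0.15)
  switch(task,
         walking = base,
         sit_to_stand = utils::modifyList(base, list(artefact_amp = 0.12)),
         pick_and_drop = base,
         standing = base,
         stairs = utils::modifyList(base, list(
           freq = 0.9 * profile$step_frequency,
           harmonics = 1.1 * profile$omega_harmonics,
           pulse = 1.1 * profile$pulse_amplitude,
           artefact_amp = 0.16)),
         running = utils::modifyList(base, list(
           freq = 1.33 * profile$step_frequency,
           harmonics = 1.7 * profile$omega_harmonics,
           pulse = (181 / 44) * profile$pulse_amplitude,
           width = 0.008,
           artefact_amp = 0.35)),
         stop(sprintf("unknown task '%s'", task), call. = FALSE))
}

# Nominal global extrema implied by a profile (used to scale perturbations
# when no calibrated thresholds are supplied).
profile_nominals <- function(profile) {
  # expected global extrema over a multi-step trial: the largest touchdown
  # of ~50 jittered steps sits about two lognormal sds above the median,
  # riding on the band-limited harmonic background of the gait cycle
  B <- profile$pulse_amplitude * profile$pulse_width * exp(0.5)
  jit <- 1 + 2 * profile$pulse_jitter
  f <- profile$step_frequency
  harm_alpha <- sum(profile$omega_harmonics * 2 * pi * seq_along(profile$omega_harmonics) * f)
  list(omega_global = sum(profile$omega_harmonics) + B * jit,
       alpha_global = profile$pulse_amplitude * jit + harm_alpha)
}

# Damped-sine recovery transient: shape, its derivative, and the
# oscillation frequency that makes the derivative peak / value peak ratio
# match the alpha/omega global-threshold ratio (so one transient exceeds
# both thresholds by the same scale).
recovery_transient <- function(t, t0, amp_omega, ratio_alpha_omega, tau = 0.2) {
  g <- function(fp) {
    u <- seq(0, 5 * tau, length.out = 2000L)
    s <- exp(-u / tau) * sin(2 * pi * fp * u)
    ds <- exp(-u / tau) * (2 * pi * fp * cos(2 * pi * fp * u) - sin(2 * pi * fp * u) / tau)
    max(abs(ds)) / max(abs(s))
  }
  fp <- stats::uniroot(function(f) g(f) - ratio_alpha_omega,
                       lower = 0.2, upper = 80, tol = 1e-3)$root
  u <- t - t0
  act <- u >= 0
  s <- numeric(length(t)); ds <- numeric(length(t))
  s[act] <- exp(-u[act] / tau) * sin(2 * pi * fp * u[act])
  ds[act] <- exp(-u[act] / tau) *
    (2 * pi * fp * cos(2 * pi * fp * u[act]) - sin(2 * pi * fp * u[act]) / tau)
  uu <- seq(0, 5 * tau, length.out = 2000L)
  smax <- max(abs(exp(-uu / tau) * sin(2 * pi * fp * uu)))
  C <- amp_omega / smax
  list(omega = C * s, alpha = C * ds, fp = fp, tau = tau)
}

#' Specification of one synthetic trial
#'
#' @param task One of `"walking"`, `"running"`, `"standing"`,
#'   `"sit_to_stand"`, `"stairs"`, `"pick_and_drop"`.
#' @param perturbation `NULL`, or a list with `type` (`"trip"`, `"slip"`,
#'   `"anterior_loss"`, `"posterior_loss"`), optional `onset` (seconds) and
#'   `scale` (peak magnitude as a multiple of the global thresholds;
#'   default 1.5, must exceed 1 for a detectable event).
#' @param duration Trial duration, seconds.
#' @return A list of class `trial_spec`.
#' @export
trial_spec <- function(task, perturbation = NULL, duration = 12) {
  task <- match.arg(task, c("walking", "running", "standing", "sit_to_stand",
                            "stairs", "pick_and_drop"))
  if (!is.null(perturbation)) {
    perturbation$type <- match.arg(perturbation$type,
                                   c("trip", "slip", "anterior_loss",
                                     "posterior_loss"))
    if (is.null(perturbation$scale)) perturbation$scale <- 1.5
    if (perturbation$scale <= 1)
      stop("invalid trial spec: perturbation scale must exceed 1", call. = FALSE)
    walkish <- perturbation$type %in% c("trip", "slip")
    if (walkish && task != "walking")
      stop("invalid trial spec: trip/slip perturbations require walking",
           call. = FALSE)
    if (!walkish && task != "standing")
      stop("invalid trial spec: loss-of-balance perturbations require standing",
           call. = FALSE)
    if (!is.null(perturbation$onset) &&
        (perturbation$onset <= 0 || perturbation$onset >= duration))
      stop("invalid trial spec: perturbation onset outside the trial",
           call. = FALSE)
  }
  structure(list(task = task, perturbation = perturbation, duration = duration),
            class = "trial_spec")
}

#' Generate one labelled synthetic trial
#'
#' Builds the noise-free angular velocity and its exact analytic derivative
#' for the requested task, injects the perturbation transient (a damped
#' sinusoid whose sign encodes the initial pitch direction and whose peaks
#' exceed `scale` times the global thresholds in *both* signals, with the
#' regular stepping suppressed during the response), and adds measurement
#' noise: Gaussian per sample on both signals plus, in the measured
#' `omega_y` only, sporadic single-sample impact artefacts at touchdowns
#' and jolts (the component that numerical differentiation amplifies into
#' spurious angular-acceleration extrema; the directly measured
#' acceleration is unaffected).
#'
#' @param spec A [trial_spec].
#' @param profile A [gait_profile].
#' @param thresholds Optional calibrated `personalised_thresholds` used to
#'   scale the perturbation; profile nominals are used otherwise.
#' @param seed Integer seed fixing the realisation.
#' @return A list: `kin` (the measured [kinematics_series]) and `truth`
#'   (task, perturbed flag, type, onset, preceding task, step times, and
#'   the noise-free `omega_true` / `alpha_true` vectors).
#' @export
generate_trial <- function(spec, profile = gait_profile(), thresholds = NULL,
                           seed = NULL) {
  if (!inherits(spec, "trial_spec")) stop("`spec` must be a trial_spec", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / profile$sample_rate
  t <- seq(0, spec$duration - dt, by = dt)
  n <- length(t)
  pars <- task_params(spec$task, profile)
  per <- 1 / pars$freq

  omega <- numeric(n)
  alpha <- numeric(n)
  step_times <- numeric(0)
  step_amps <- numeric(0)
  artefact_times <- numeric(0)
  artefact_amps <- numeric(0)

  gaiting <- spec$task %in% c("walking", "running", "stairs", "sit_to_stand",
                              "pick_and_drop")
  walk_on <- NA_real_; walk_off <- NA_real_
  if (spec$task %in% c("walking", "running", "stairs")) {
    walk_on <- 1.5; walk_off <- spec$duration - 1
  } else if (spec$task == "sit_to_stand") {
    walk_on <- 4; walk_off <- spec$duration - 1
  } else if (spec$task == "pick_and_drop") {
    gaiting <- FALSE # stance, bend, carry modelled without full gait
  }

  truth_type <- "none"; truth_onset <- NA_real_; preceding <- spec$task
  pert <- spec$perturbation

  if (gaiting) {
    env <- gait_envelope(t, walk_on, walk_off)
    H <- numeric(n); dH <- numeric(n)
    for (h in seq_along(pars$harmonics)) {
      wh <- 2 * pi * h * pars$freq
      H <- H + pars$harmonics[h] * sin(wh * (t - walk_on))
      dH <- dH + pars$harmonics[h] * wh * cos(wh * (t - walk_on))
    }
    omega <- env$value * H
    alpha <- env$deriv * H + env$value * dH
    full_on <- walk_on + 0.5; full_off <- walk_off - 0.5
    first_td <- full_on + profile$touchdown_phase * per
    step_times <- if (first_td <= full_off) seq(first_td, full_off, by = per)
                  else numeric(0)
  } else if (spec$task == "standing" ||
             (!is.null(pert) && !pert$type %in% c("trip", "slip"))) {
    sway <- 2 * pi * 0.3
    omega <- 0.01 * sin(sway * t)
    alpha <- 0.01 * sway * cos(sway * t)
  }

  nominal <- if (!is.null(thresholds)) {
    list(omega_global = max(thresholds$omega_y$global_max,
                            -thresholds$omega_y$global_min),
         alpha_global = max(thresholds$alpha_y$global_max,
                            -thresholds$alpha_y$global_min))
  } else profile_nominals(profile)

  if (spec$task == "pick_and_drop") {
    # slow trunk bend reaching well past the angular-velocity threshold,
    # with a negligible angular-acceleration footprint, plus a drop jolt
    # artefact at the bend peak (measured omega only)
    t_bend <- spec$duration / 2
    bd <- bump_train(t, t_bend, 1.4 * nominal$omega_global, 0.35)
    omega <- omega + bd$value
    alpha <- alpha + bd$deriv
    artefact_times <- c(artefact_times, t_bend)
    artefact_amps <- c(artefact_amps, abs(stats::rnorm(1, 0.6, 0.1)))
  }

  if (spec$task == "sit_to_stand") {
    # trunk flexion-extension of the rise, below the detection thresholds
    rise <- bump_train(t, c(2.2, 3.0), c(0.8, -0.6) * nominal$omega_global / 1.6,
                       0.35)
    omega <- omega + rise$value
    alpha <- alpha + rise$deriv
  }

  if (!is.null(pert)) {
    truth_type <- pert$type
    sgn <- if (pert$type %in% c("trip", "anterior_loss")) 1 else -1
    t0 <- pert$onset
    if (is.null(t0))
      t0 <- if (pert$type %in% c("trip", "slip")) walk_on + 3.1 else spec$duration / 2
    truth_onset <- t0
    preceding <- if (pert$type %in% c("trip", "slip")) "walking" else "standing"
    tr <- recovery_transient(t, t0, sgn * pert$scale * nominal$omega_global,
                             nominal$alpha_global / nominal$omega_global)
    omega <- omega + tr$omega
    alpha <- alpha + tr$alpha
    # stepping is disrupted during the recovery response
    step_times <- step_times[step_times < t0 | step_times > t0 + 3 * tr$tau]
  }

  if (length(step_times) > 0L) {
    amps <- profile$pulse_amplitude *
      exp(stats::rnorm(length(step_times), 0, profile$pulse_jitter))
    B <- amps * pars$pulse / profile$pulse_amplitude * pars$width * exp(0.5)
    td <- bump_train(t, step_times, B, pars$width)
    omega <- omega + td$value
    alpha <- alpha + td$deriv
    step_amps <- amps * pars$pulse / profile$pulse_amplitude
    hit <- stats::runif(length(step_times)) < profile$artefact_prob
    # the impact jerk sits at the onset of the touchdown transient
    artefact_times <- c(artefact_times, step_times[hit] - pars$width)
    artefact_amps <- c(artefact_amps,
                       abs(stats::rnorm(sum(hit), pars$artefact_amp,
                                        pars$artefact_amp / 3)))
  }

  noisy <- profile$noise_omega > 0 || profile$noise_alpha > 0
  if (!noisy) {
    artefact_times <- numeric(0)
    artefact_amps <- numeric(0)
  }
  artefact_signs <- sample(c(-1, 1), length(artefact_times), replace = TRUE)
  omega_meas <- omega + stats::rnorm(n, 0, profile$noise_omega)
  alpha_meas <- alpha + stats::rnorm(n, 0, profile$noise_alpha)
  if (length(artefact_times) > 0L) {
    # a ~20 ms impact transient: two consecutive samples of the same sign
    idx <- pmin(pmax(round(artefact_times / dt) + 1L, 1L), n)
    spike <- artefact_signs * artefact_amps
    omega_meas[idx] <- omega_meas[idx] + spike
    idx2 <- pmin(idx + 1L, n)
    omega_meas[idx2] <- omega_meas[idx2] + spike
  }

  # noise-free per-step angular-acceleration peaks (calibration ground truth)
  alpha_peaks <- if (length(step_times) > 0L) {
    vapply(step_times, function(tk) {
      w <- t >= tk - 3 * pars$width & t <= tk + 3 * pars$width
      if (any(w)) max(alpha[w]) else NA_real_
    }, numeric(1))
  } else numeric(0)

  list(kin = kinematics_series(t, omega_meas, alpha_meas),
       truth = list(task = spec$task, perturbed = !is.null(pert),
                    type = truth_type, onset = truth_onset,
                    preceding = preceding,
                    step_times = step_times,
                    step_frequency = if (gaiting) pars$freq else NA_real_,
                    alpha_peaks = alpha_peaks,
                    artefact_times = artefact_times,
                    artefact_amps = artefact_signs * artefact_amps,
                    omega_true = omega, alpha_true = alpha))
}

#' Generate a baseline walking trial
#'
#' Convenience wrapper producing the unperturbed walking trials used for
#' threshold calibration (quiet stance lead-in and lead-out around steady
#' walking, emulating overground walking at the target speed of about
#' 1.4 m/s).
#'
#' @param profile A [gait_profile].
#' @param duration Trial duration, seconds (default 30).
#' @param seed Integer seed.
#' @return The measured [kinematics_series] with the ground truth attached
#'   as attribute `truth`.
#' @export
generate_baseline <- function(profile = gait_profile(), duration = 30,
                              seed = NULL) {
  trial <- generate_trial(trial_spec("walking", duration = duration),
                          profile, seed = seed)
  out <- trial$kin
  attr(out, "truth") <- trial$truth
  out
}

#' Generate a raw four-package cluster recording
#'
#' Wraps the rigid-body forward model around a synthetic trial: the
#' noise-free trunk angular state (transverse-axis rotation) drives the
#' four accelerometer readings, to which per-channel Gaussian noise is
#' added (`noise_accel` on accelerometers, `noise_omega` on each
#' gyroscope). The noise-free cluster solve recovers the trial's true
#' angular acceleration exactly.
#'
#' @param spec A [trial_spec].
#' @param profile A [gait_profile].
#' @param geom A [cluster_geometry].
#' @param seed Integer seed.
#' @return A list: `cluster` (the recording data frame, see
#'   [read_cluster_csv] for the format), `truth`, and `kin` (the measured
#'   single-IMU style series of the same realisation).
#' @export
generate_cluster_trial <- function(spec, profile = gait_profile(),
                                   geom = cluster_geometry(), seed = NULL) {
  trial <- generate_trial(spec, profile, seed = seed)
  truth <- trial$truth
  n <- length(truth$omega_true)
  t <- trial$kin$t
  omega3 <- cbind(0, truth$omega_true, 0)
  alpha3 <- cbind(0, truth$alpha_true, 0)
  a0 <- matrix(c(0, 0, 9.81), n, 3L, byrow = TRUE)
  rs <- list(geom$r10, geom$r20, geom$r30)
  acc <- vector("list", 4L)
  acc[[1L]] <- a0
  for (i in 1:3) {
    R <- matrix(rs[[i]], n, 3L, byrow = TRUE)
    acc[[i + 1L]] <- a0 + row_cross(alpha3, R) +
      row_cross(omega3, row_cross(omega3, R))
  }
  # impact artefacts are mechanical, hence common-mode across the rigidly
  # mounted gyroscopes; the accelerometer channels (and so the cluster
  # angular-acceleration solve) are unaffected
  art <- numeric(n)
  if (length(truth$artefact_times) > 0L) {
    dt <- t[2L] - t[1L]
    idx <- pmin(pmax(round(truth$artefact_times / dt) + 1L, 1L), n)
    art[idx] <- art[idx] + truth$artefact_amps
    idx2 <- pmin(idx + 1L, n)
    art[idx2] <- art[idx2] + truth$artefact_amps
  }
  cols <- list(t = t)
  for (i in 0:3) {
    am <- acc[[i + 1L]] + matrix(stats::rnorm(3L * n, 0, profile$noise_accel),
                                 n, 3L)
    wm <- omega3 + matrix(stats::rnorm(3L * n, 0, profile$noise_omega), n, 3L)
    wm[, 2L] <- wm[, 2L] + art
    cols[[paste0("s", i, "_ax")]] <- am[, 1L]
    cols[[paste0("s", i, "_ay")]] <- am[, 2L]
    cols[[paste0("s", i, "_az")]] <- am[, 3L]
    cols[[paste0("s", i, "_wx")]] <- wm[, 1L]
    cols[[paste0("s", i, "_wy")]] <- wm[, 2L]
    cols[[paste0("s", i, "_wz")]] <- wm[, 3L]
  }
  list(cluster = as.data.frame(cols), truth = truth, kin = trial$kin)
}

# Largest-remainder allocation of n trials over mix fractions.
allocate_mix <- function(n, mix) {
  raw <- n * mix / sum(mix)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(mix))
}

#' Default benchmark trial mix
#'
#' The trial composition of the validation study: 179 perturbed trials (74
#' trips, 16 slips, 62 anterior and 27 posterior losses of balance) and 448
#' ADLs (84 sit-to-stand, 168 walking, 72 running, 82 staircase, 42
#' pick-and-drop), 627 trials in total.
#'
#' @return Named integer vector of trial counts.
#' @export
benchmark_mix <- function() {
  c(trip = 74, slip = 16, anterior_loss = 62, posterior_loss = 27,
    sit_to_stand = 84, walking = 168, running = 72, stairs = 82,
    pick_and_drop = 42)
}

#' Generate a labelled benchmark set
#'
#' Produces a reproducible corpus of synthetic trials with the requested
#' class mix (default: the study composition, [benchmark_mix]) for
#' end-to-end evaluation of the framework.
#'
#' @param n_trials Number of trials (default 627).
#' @param mix Named numeric vector of class fractions or counts; names are
#'   perturbation types (`trip`, `slip`, `anterior_loss`, `posterior_loss`)
#'   or ADL tasks.
#' @param seed Integer seed (drives every trial realisation).
#' @param profile A [gait_profile].
#' @param scale Perturbation magnitude scale (default 1.5 times the global
#'   thresholds).
#' @param duration Per-trial duration, seconds.
#' @return A list: `trials` (list of [generate_trial] outputs) and `labels`
#'   (data frame with `trial`, `task`, `perturbed`, `type`).
#' @export
generate_benchmark_set <- function(n_trials = 627, mix = benchmark_mix(),
                                   seed = 1, profile = gait_profile(),
                                   scale = 1.5, duration = 12) {
  pert_types <- c("trip", "slip", "anterior_loss", "posterior_loss")
  if (n_trials == 0)
    return(list(trials = list(),
                labels = data.frame(trial = integer(0), task = character(0),
                                    perturbed = logical(0), type = character(0))))
  counts <- allocate_mix(n_trials, mix)
  set.seed(seed)
  kinds <- rep(names(counts), counts)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  trials <- vector("list", n_trials)
  labels <- data.frame(trial = seq_len(n_trials), task = NA_character_,
                       perturbed = FALSE, type = "none",
                       stringsAsFactors = FALSE)
  for (i in seq_len(n_trials)) {
    kind <- kinds[i]
    if (kind %in% pert_types) {
      task <- if (kind %in% c("trip", "slip")) "walking" else "standing"
      sp <- trial_spec(task, perturbation = list(type = kind, scale = scale),
                       duration = duration)
      labels$task[i] <- task
      labels$perturbed[i] <- TRUE
      labels$type[i] <- kind
    } else {
      sp <- trial_spec(kind, duration = duration)
      labels$task[i] <- kind
    }
    trials[[i]] <- generate_trial(sp, profile, seed = trial_seeds[i])
  }
  list(trials = trials, labels = labels)
}
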