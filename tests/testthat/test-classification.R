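test_that("running windows are periodic ADLs decided at step 1", {
  th <- fixture_thresholds()
  x <- generate_trial(trial_spec("running"), default_profile(),
                      thresholds = th, seed = 13)
  calls <- classify_trial(x$kin, th)
  expect_gte(length(calls), 1) # running does exceed walking thresholds
  for (cl in calls) {
    expect_false(cl$is_recovery)
    expect_equal(cl$trace$step, 1L)
    expect_equal(cl$trace$condition, "periodic_ADL")
  }
})

test_that("trip windows are recoveries via correlated outliers", {
  th <- fixture_thresholds()
  x <- generate_trial(trial_spec("walking",
                                 perturbation = list(type = "trip", scale = 1.5)),
                      default_profile(), thresholds = th, seed = 7)
  calls <- classify_trial(x$kin, th)
  expect_length(calls, 1)
  cl <- calls[[1]]
  expect_true(cl$is_recovery)
  expect_equal(cl$type, "trip")
  expect_equal(cl$preceding, "walking")
  expect_equal(cl$trace$condition, "correlated_outliers")
  # the deciding outlier pair is tight in time
  ev <- cl$trace$evidence
  expect_lte(abs(ev$alpha_time - ev$omega_time), 0.15)
})

test_that("step 1 leaves sparse non-outlier windows undecided", {
  th <- fixture_thresholds_quiet()
  dt <- 0.01
  t <- seq(0, 12 - dt, dt)
  # two moderate, similar pulses: neither periodic (3+ repetitions) nor an
  # outlier pair (equal magnitudes)
  p <- function(t0) exp(-(t - t0)^2 / (2 * 0.03^2))
  alpha <- 20 * (p(5) + p(5.6)) - 20 * (p(5.1) + p(5.7))
  omega <- 0.5 * (p(5) + p(5.6))
  kin <- kinematics_series(t, omega, alpha)
  w <- structure(list(onset = 4.8, offset = 6.0,
                      truncated_start = FALSE, truncated_end = FALSE),
                 class = "observation_window")
  s1 <- step1_periodicity_vs_outliers(w, kin, th)
  expect_equal(s1$verdict, "undecided")
})

test_that("step 2 flags transient short-lag frequency content only", {
  th <- fixture_thresholds()
  # an unperturbed walking stretch: peak lags are multiples of the step
  # period, so nothing transient is flagged
  base <- generate_baseline(default_profile(), duration = 30, seed = 102)
  w <- structure(list(onset = 10, offset = 12,
                      truncated_start = FALSE, truncated_end = FALSE),
                 class = "observation_window")
  expect_equal(step2_frequency_content(w, base, th)$verdict, "undecided")
  # pure noise: no quartile-outlier peaks
  set.seed(6)
  noise <- kinematics_series(seq(0, 12, 0.01), rnorm(1201, 0, 0.02),
                             rnorm(1201, 0, 0.3))
  w2 <- structure(list(onset = 5, offset = 6,
                       truncated_start = FALSE, truncated_end = FALSE),
                  class = "observation_window")
  expect_equal(step2_frequency_content(w2, noise, th)$verdict, "undecided")
})

test_that("step 3 requires the outlier pair to be time-correlated", {
  th <- fixture_thresholds_quiet()
  dt <- 0.01
  t <- seq(0, 20 - dt, dt)
  spike <- function(t0, w = 0.02) exp(-(t - t0)^2 / (2 * w^2))
  # correlated pair: omega and alpha outliers at the same instant against a
  # quiet context
  mk <- function(lag) {
    om <- 0.1 * sin(2 * pi * 0.4 * t) + 1.5 * th$omega_y$global_max * spike(10)
    al <- 3 * sin(2 * pi * 0.4 * t) +
      1.5 * th$alpha_y$global_max * spike(10 + lag)
    kinematics_series(t, om, al)
  }
  w <- structure(list(onset = 9.8, offset = 10.6,
                      truncated_start = FALSE, truncated_end = FALSE),
                 class = "observation_window")
  expect_equal(step3_boundary_outliers(w, mk(0), th)$verdict, "recovery")
  expect_equal(step3_boundary_outliers(w, mk(0.4), th)$verdict, "ADL")
})

test_that("preceding task is identified from the pre-onset interval", {
  th <- fixture_thresholds()
  prof <- default_profile()
  # quiet stance before a mid-trial onset
  stand <- generate_trial(trial_spec("standing"), prof, seed = 61)$kin
  expect_equal(classify_preceding_task(stand, 8, th)$task, "standing")
  # steady walking before the onset
  walk <- generate_trial(trial_spec("walking", duration = 14), prof, seed = 62)$kin
  expect_equal(classify_preceding_task(walk, 9, th)$task, "walking")
  # running amplitudes and cadence
  run <- generate_trial(trial_spec("running", duration = 14), prof, seed = 63)$kin
  expect_equal(classify_preceding_task(run, 9, th)$task, "running")
})

test_that("perturbation types follow the sign convention and preceding task", {
  th <- fixture_thresholds()
  prof <- default_profile()
  cases <- list(list("walking", "trip"), list("walking", "slip"),
                list("standing", "anterior_loss"), list("standing", "posterior_loss"))
  for (cs in cases) {
    x <- generate_trial(trial_spec(cs[[1]],
                                   perturbation = list(type = cs[[2]], scale = 1.5)),
                        prof, thresholds = th, seed = 70)
    calls <- classify_trial(x$kin, th)
    expect_length(calls, 1)
    expect_true(calls[[1]]$is_recovery)
    expect_equal(calls[[1]]$type, cs[[2]])
  }
})

test_that("negating both signals swaps the perturbation direction labels", {
  th <- fixture_thresholds()
  x <- generate_trial(trial_spec("walking",
                                 perturbation = list(type = "trip", scale = 1.5)),
                      default_profile(), thresholds = th, seed = 71)
  calls <- classify_trial(x$kin, th)
  expect_equal(calls[[1]]$type, "trip")
  flipped <- kinematics_series(x$kin$t, -x$kin$omega_y, -x$kin$alpha_y)
  # thresholds must describe the flipped signal; the generator's baselines
  # are direction-asymmetric, so recalibrate on flipped baselines
  bases <- lapply(1:3, function(i)
    generate_baseline(default_profile(), duration = 30, seed = 100 + i))
  th_f <- calibrate_thresholds(lapply(bases, function(b)
    kinematics_series(b$t, -b$omega_y, -b$alpha_y)))
  calls_f <- classify_trial(flipped, th_f)
  expect_length(calls_f, 1)
  expect_true(calls_f[[1]]$is_recovery)
  expect_equal(calls_f[[1]]$type, "slip")
  # equivalently, flipping the configured sign convention swaps the label
  cfg_f <- nearfall_config(sign_convention = -1)
  calls_c <- classify_trial(flipped, th_f, config = cfg_f)
  expect_equal(calls_c[[1]]$type, "trip")
})

test_that("trials compose: empty for pure walking, two calls for two events", {
  th <- fixture_thresholds()
  prof <- default_profile()
  walk <- generate_trial(trial_spec("walking"), prof, seed = 80)$kin
  expect_length(classify_trial(walk, th), 0)
  # two well-separated hand-injected transients on a standing trial
  stand <- generate_trial(trial_spec("standing", duration = 20), prof, seed = 81)$kin
  tr1 <- hand_transient(stand$t, 6, 1.5 * th$omega_y$global_max)
  tr2 <- hand_transient(stand$t, 14, -1.5 * th$omega_y$global_max)
  scl <- 1.4 * th$alpha_y$global_max /
    max(abs(hand_transient(stand$t, 6, 1.5 * th$omega_y$global_max)$alpha))
  kin <- kinematics_series(stand$t,
                           stand$omega_y + tr1$omega + tr2$omega,
                           stand$alpha_y + (tr1$alpha + tr2$alpha) * max(scl, 1))
  calls <- classify_trial(kin, th)
  expect_length(calls, 2)
  expect_true(all(vapply(calls, `[[`, logical(1), "is_recovery")))
  expect_lt(calls[[1]]$window$onset, calls[[2]]$window$onset)
  expect_equal(calls[[1]]$type, "anterior_loss")
  expect_equal(calls[[2]]$type, "posterior_loss")
})

test_that("every window receives exactly one terminal verdict with a trace", {
  th <- fixture_thresholds()
  prof <- default_profile()
  for (s in 1:4) {
    x <- generate_trial(trial_spec("running"), prof, seed = 90 + s)
    calls <- classify_trial(x$kin, th)
    for (cl in calls) {
      expect_true(cl$trace$step %in% 1:3)
      expect_true(cl$trace$condition %in%
                    c("periodic_ADL", "correlated_outliers",
                      "transient_frequency", "boundary_outliers", "default_ADL"))
      expect_equal(cl$is_recovery,
                   cl$trace$condition %in%
                     c("correlated_outliers", "transient_frequency",
                       "boundary_outliers"))
    }
  }
})
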