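test_that("the calibration baseline itself contains no observation window", {
  th <- fixture_thresholds()
  base <- generate_baseline(default_profile(), duration = 30, seed = 101)
  expect_length(detect_windows(base, th), 0)
})

test_that("a joint-signal transient yields exactly one window containing it", {
  th <- fixture_thresholds()
  x <- generate_trial(trial_spec("walking",
                                 perturbation = list(type = "trip", scale = 1.3)),
                      default_profile(), thresholds = th, seed = 31)
  w <- detect_windows(x$kin, th)
  expect_length(w, 1)
  expect_lte(w[[1]]$onset, x$truth$onset + 0.1)
  expect_gte(w[[1]]$offset, x$truth$onset)
})

test_that("an angular-velocity-only anomaly is not a window", {
  th <- fixture_thresholds()
  for (s in 1:3) {
    x <- generate_trial(trial_spec("pick_and_drop"), default_profile(),
                        thresholds = th, seed = 40 + s)
    expect_length(detect_windows(x$kin, th), 0)
  }
})

test_that("raising the detection ratio never increases the window count", {
  th <- fixture_thresholds()
  x <- generate_trial(trial_spec("walking",
                                 perturbation = list(type = "trip", scale = 1.6)),
                      default_profile(), thresholds = th, seed = 33)
  counts <- vapply(c(1.05, 1.15, 1.3, 1.6, 2.5),
                   function(r) length(detect_windows(x$kin, th, ratio = r)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is shift-equivariant", {
  th <- fixture_thresholds()
  x <- generate_trial(trial_spec("walking",
                                 perturbation = list(type = "slip", scale = 1.5)),
                      default_profile(), thresholds = th, seed = 35)
  w1 <- detect_windows(x$kin, th)
  shifted <- kinematics_series(x$kin$t + 11.7, x$kin$omega_y, x$kin$alpha_y)
  w2 <- detect_windows(shifted, th)
  expect_equal(length(w1), length(w2))
  expect_equal(w2[[1]]$onset, w1[[1]]$onset + 11.7, tolerance = 1e-9)
  expect_equal(w2[[1]]$offset, w1[[1]]$offset + 11.7, tolerance = 1e-9)
})

test_that("onset lands immediately after the zero crossing preceding the pulse", {
  th <- fixture_thresholds_quiet()
  # quiet stance with one hand-built transient at a known onset
  dt <- 0.01
  t <- seq(0, 12 - dt, dt)
  t0 <- 6
  tr <- hand_transient(t, t0, 1.6 * th$omega_y$global_max)
  scl <- 1.4 * th$alpha_y$global_max / max(abs(tr$alpha))
  # a faint sway background that crosses zero exactly at t0, so the last
  # zero crossing before the transient is at the transient onset
  sway <- 0.5 * sin(2 * pi * 0.4 * (t - t0))
  kin <- kinematics_series(t, tr$omega * 1, sway + tr$alpha * max(scl, 1))
  w <- detect_windows(kin, th)
  expect_length(w, 1)
  # alpha is exactly zero before t0 and jumps at t0: the last sign change
  # precedes t0 by construction, so the refined onset sits at t0 +- one sample
  expect_equal(w[[1]]$onset, t0, tolerance = dt + 1e-9)
  expect_false(w[[1]]$truncated_start)
})

test_that("pulse separation drives window merging", {
  th <- fixture_thresholds_quiet()
  dt <- 0.01
  t <- seq(0, 20 - dt, dt)
  per <- th$step_period
  amp_w <- 1.6 * th$omega_y$global_max
  mk <- function(gap) {
    tr1 <- hand_transient(t, 6, amp_w)
    tr2 <- hand_transient(t, 6 + gap, amp_w)
    om <- tr1$omega + tr2$omega
    al <- tr1$alpha + tr2$alpha
    scl <- 1.4 * th$alpha_y$global_max / max(abs(hand_transient(t, 6, amp_w)$alpha))
    kinematics_series(t, om, al * max(scl, 1))
  }
  # two pulses three step periods apart: two disjoint windows
  w_far <- detect_windows(mk(3 * per), th)
  expect_length(w_far, 2)
  expect_lt(w_far[[1]]$offset, w_far[[2]]$onset)
  # closer than one step period: a single merged window covering both
  w_near <- detect_windows(mk(0.8 * per), th)
  expect_length(w_near, 1)
  expect_gte(w_near[[1]]$offset, 6 + 0.8 * per)
})

test_that("windows at the record boundary are kept and flagged truncated", {
  th <- fixture_thresholds_quiet()
  dt <- 0.01
  t <- seq(0, 8 - dt, dt)
  tr <- hand_transient(t, 7.7, 1.6 * th$omega_y$global_max)
  scl <- 1.4 * th$alpha_y$global_max / max(abs(tr$alpha))
  kin <- kinematics_series(t, tr$omega, tr$alpha * max(scl, 1))
  w <- detect_windows(kin, th)
  expect_length(w, 1)
  expect_true(w[[1]]$truncated_end)
  expect_equal(w[[1]]$offset, max(t))
})

test_that("windows are disjoint, ordered, and serialisable", {
  th <- fixture_thresholds()
  x <- generate_trial(trial_spec("walking",
                                 perturbation = list(type = "trip", scale = 1.5)),
                      default_profile(), thresholds = th, seed = 44)
  w <- detect_windows(x$kin, th)
  df <- windows_to_df(w)
  expect_true(all(df$onset < df$offset))
  if (nrow(df) > 1) expect_true(all(utils::head(df$offset, -1) < df$onset[-1]))
  expect_length(detect_windows(generate_trial(trial_spec("standing"),
                                              default_profile(),
                                              seed = 45)$kin, th), 0)
})
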