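# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_profile <- function(...) gait_profile(...)

quiet_profile <- function(...) {
  gait_profile(noise_omega = 0, noise_alpha = 0, noise_accel = 0, ...)
}

# calibrated thresholds on three default-profile baselines
fixture_thresholds <- function() {
  fixture("thresholds", function() {
    bases <- lapply(1:3, function(i)
      generate_baseline(default_profile(), duration = 30, seed = 100 + i))
    calibrate_thresholds(bases)
  })
}

# noise-free counterpart
fixture_thresholds_quiet <- function() {
  fixture("thresholds_quiet", function() {
    bases <- lapply(1:3, function(i)
      generate_baseline(quiet_profile(), duration = 30, seed = 100 + i))
    calibrate_thresholds(bases)
  })
}

# a damped-sine recovery transient built independently of the generator,
# for hand-constructed window/classification fixtures
hand_transient <- function(t, t0, amp, fp = 4, tau = 0.2) {
  u <- t - t0
  act <- u >= 0
  s <- numeric(length(t)); ds <- numeric(length(t))
  s[act] <- exp(-u[act] / tau) * sin(2 * pi * fp * u[act])
  ds[act] <- exp(-u[act] / tau) *
    (2 * pi * fp * cos(2 * pi * fp * u[act]) - sin(2 * pi * fp * u[act]) / tau)
  list(omega = amp * s, alpha = amp * ds)
}
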