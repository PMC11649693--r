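test_that("mean angular velocity is the component-wise mean of the four gyros", {
  w <- list(c(0, 1, 0), c(0, 1, 0), c(0, 1, 0), c(0, 1, 0))
  s <- cluster_sample(0, a = rep(list(c(0, 0, 0)), 4), w = w)
  expect_equal(mean_angular_velocity(s), c(0, 1, 0))

  w <- list(c(0, 1, 0), c(0, 2, 0), c(0, 3, 0), c(0, 4, 0))
  s <- cluster_sample(0, a = rep(list(c(0, 0, 0)), 4), w = w)
  expect_equal(mean_angular_velocity(s)[2], 2.5)

  set.seed(1)
  w <- lapply(1:4, function(i) rnorm(3))
  s <- cluster_sample(0, a = rep(list(c(0, 0, 0)), 4), w = w)
  expect_equal(mean_angular_velocity(s), colMeans(do.call(rbind, w)))
})

test_that("cluster solve inverts the rigid-body forward model", {
  geom <- cluster_geometry()
  # static cluster: no rotation
  s <- cluster_sample(0, a = rep(list(c(0, 0, 9.81)), 4),
                      w = rep(list(c(0, 0, 0)), 4))
  expect_equal(cluster_angular_acceleration(s, geom), c(0, 0, 0))

  s <- rigid_body_forward_model(c(0, 5, 0), c(0, 1, 0), c(0, 0, 9.81), geom)
  expect_lt(max(abs(cluster_angular_acceleration(s, geom) - c(0, 5, 0))), 1e-9)

  set.seed(7)
  errs <- replicate(200, {
    al <- runif(3, -500, 500)
    om <- runif(3, -20, 20)
    a0 <- rnorm(3, 0, 5)
    s <- rigid_body_forward_model(al, om, a0, geom)
    max(abs(cluster_angular_acceleration(s, geom) - al))
  })
  expect_lt(max(errs), 1e-8)
})

test_that("forward model matches rigid-body closed forms", {
  geom <- cluster_geometry()
  # pure translation
  s <- rigid_body_forward_model(c(0, 0, 0), c(0, 0, 0), c(1, 2, 3), geom)
  for (i in 1:4) expect_equal(s$a[[i]], c(1, 2, 3))
  # pure spin about z: a_i - a0 is the centripetal field -w^2 * r_perp
  w <- 3
  s <- rigid_body_forward_model(c(0, 0, 0), c(0, 0, w), c(0, 0, 0), geom)
  for (pair in list(list(2L, geom$r10), list(3L, geom$r20), list(4L, geom$r30))) {
    r <- pair[[2]]
    cent <- -w^2 * c(r[1], r[2], 0) # component perpendicular to the spin axis
    expect_equal(s$a[[pair[[1]]]], cent, tolerance = 1e-12)
  }
})

test_that("degenerate cluster geometry is rejected", {
  expect_error(cluster_geometry(r10 = c(0.08, 0, 0), r20 = c(0.16, 0, 0),
                                r30 = c(0, 0, 0.05)),
               "singular")
})

test_that("difference quotients are exact on low-order polynomials", {
  t <- seq(0, 1, by = 0.1)
  cd <- central_difference(3 * t, 0.1)
  expect_true(is.na(cd[1]) && is.na(cd[length(cd)]))
  expect_equal(cd[2:(length(cd) - 1)], rep(3, length(cd) - 2))
  bd <- backward_difference(3 * t, 0.1)
  expect_true(is.na(bd[1]))
  expect_equal(bd[-1], rep(3, length(bd) - 1))
  expect_equal(backward_difference(rep(5, 10), 0.1)[-1], rep(0, 9))
  # they agree exactly on linear signals (interior points)
  f <- -2 + 0.7 * t
  expect_equal(central_difference(f, 0.1)[2:10], backward_difference(f, 0.1)[2:10])
  expect_error(central_difference(c(1, 2), 0.1), "at least 3")
  expect_error(backward_difference(1, 0.1), "at least 2")
})

test_that("central difference error on a sinusoid obeys the Taylor bound", {
  dt <- 0.01
  t <- seq(0, 2, by = dt)
  est <- central_difference(sin(2 * pi * t), dt)
  true <- 2 * pi * cos(2 * pi * t)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(est[interior] - true[interior])), (2 * pi)^3 * dt^2 / 6)
})

test_that("white-noise variance propagates as sigma^2/(2 dt^2) and 2 sigma^2/dt^2", {
  set.seed(11)
  dt <- 0.01
  sigma <- 0.5
  x <- rnorm(1e6, 0, sigma)
  v_c <- var(central_difference(x, dt), na.rm = TRUE)
  v_b <- var(backward_difference(x, dt), na.rm = TRUE)
  expect_equal(v_c, sigma^2 / (2 * dt^2), tolerance = 0.05)
  expect_equal(v_b, 2 * sigma^2 / dt^2, tolerance = 0.05)
  expect_equal(v_b / v_c, 4, tolerance = 0.1)
})

test_that("differencing a noisy gyro is noisier than the cluster solve", {
  geom <- cluster_geometry()
  ct <- generate_cluster_trial(trial_spec("walking", duration = 20),
                               default_profile(), geom, seed = 3)
  kin <- solve_cluster_series(ct$cluster, geom)
  err_imc <- kin$alpha_y - ct$truth$alpha_true
  err_bd <- backward_difference(ct$cluster$s0_wy, 0.01) - ct$truth$alpha_true
  err_cd <- central_difference(ct$cluster$s0_wy, 0.01) - ct$truth$alpha_true
  expect_lt(sd(err_imc), sd(err_cd, na.rm = TRUE))
  expect_lt(sd(err_cd, na.rm = TRUE), sd(err_bd, na.rm = TRUE))
})

test_that("kinematics series validates its grid", {
  expect_error(kinematics_series(c(0, 0.1, 0.3), c(0, 0, 0), c(0, 0, 0)),
               "non-uniform")
  expect_error(kinematics_series(c(0, 0.1, 0.1), 1:3, 1:3), "increasing")
  ks <- kinematics_series(seq(0, 1, 0.01), rep(0, 101), rep(0, 101))
  expect_equal(sampling_interval(ks), 0.01)
})
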