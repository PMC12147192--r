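test_that("eigenfrequency follows sqrt(g/height) and rejects bad input", {
  expect_equal(eigenfrequency(9.81), 1.0)
  expect_equal(eigenfrequency(1.0), sqrt(9.81))
  expect_error(eigenfrequency(0), "positive")
  expect_error(eigenfrequency(-1), "positive")
})

test_that("passive trajectory matches the closed form and an ODE oracle", {
  st <- pendulum_state(-0.10, 0, 1.0)
  expect_equal(lipm_trajectory(st, 0), -0.10)
  expect_equal(lipm_trajectory(st, 0.2), -0.10 * cosh(sqrt(9.81) * 0.2),
               tolerance = 1e-12)
  expect_equal(round(lipm_trajectory(st, 0.2), 4), -0.1203)
  expect_error(lipm_trajectory(st, -0.1), "non-negative")

  st2 <- pendulum_state(-0.10, 0.15, 1.0)
  dt <- 1e-4
  times <- seq(0, 0.5, by = dt)
  ode <- rk4_trajectory(st2$x0, st2$v0, st2$omega, dt, length(times) - 1)
  expect_lt(max(abs(lipm_trajectory(st2, times) - ode)), 1e-9)
})

test_that("stationary time covers valid, receding and fall-over regimes", {
  expect_equal(stationary_time(pendulum_state(-0.10, 0, 1.0))$t_star, 0)
  res <- stationary_time(pendulum_state(-0.10, 0.15, 1.0))
  expect_equal(res$status, "valid")
  expect_equal(res$t_star, atanh(0.15 / (sqrt(9.81) * 0.10)) / sqrt(9.81),
               tolerance = 1e-12)
  expect_equal(round(res$t_star, 4), 0.1665)
  over <- stationary_time(pendulum_state(-0.05, 0.20, 1.0))
  expect_equal(over$status, "fall_over_pivot")
  expect_true(is.na(over$t_star))
  rec <- stationary_time(pendulum_state(-0.10, -0.05, 1.0))
  expect_equal(rec$status, "receding")
  expect_equal(rec$t_star, 0)
  expect_error(stationary_time(pendulum_state(0, 0.1, 1.0)), "Degenerate")
})

test_that("projected magnitude reproduces the worked decomposition", {
  pr <- projected_transfer_magnitude(pendulum_state(-0.10, 0.15, 1.0))
  expect_equal(pr$status, "valid")
  expect_equal(round(pr$magnitude, 4), -0.0878)
  expect_equal(round(pr$fp_component, 4), -0.1139)
  expect_equal(round(pr$v_component, 4), 0.0261)
  expect_equal(round(pr$fp_coefficient, 3), 1.139)
  expect_equal(round(pr$v_coefficient, 4), 0.1742)
  # zero-velocity identity
  pr0 <- projected_transfer_magnitude(pendulum_state(-0.10, 0, 2.0))
  expect_equal(pr0$magnitude, -0.10)
  expect_equal(pr0$fp_coefficient, 1)
  expect_equal(pr0$v_component, 0)
  # receding: minimum is the current position
  prr <- projected_transfer_magnitude(pendulum_state(-0.10, -0.2, 1.0))
  expect_equal(prr$status, "receding")
  expect_equal(prr$magnitude, -0.10)
  # fall over pivot: no magnitude
  prf <- projected_transfer_magnitude(pendulum_state(-0.05, 0.20, 1.0))
  expect_equal(prf$status, "fall_over_pivot")
  expect_true(is.na(prf$magnitude))
})

test_that("closed-form magnitude agrees with the projection to 1e-12", {
  expect_equal(closed_form_magnitude(pendulum_state(-0.10, 0, 1.3)), -0.10)
  expect_equal(round(closed_form_magnitude(pendulum_state(-0.10, 0.15, 1.0)), 5),
               -0.08779)
  expect_error(closed_form_magnitude(pendulum_state(-0.05, 0.20, 1.0)),
               "requires")
  set.seed(42)
  for (i in 1:200) {
    h <- runif(1, 0.8, 1.1)
    x0 <- runif(1, -0.25, -0.02)
    w <- sqrt(9.81 / h)
    v0 <- runif(1, 0, 0.95 * w * abs(x0))
    st <- pendulum_state(x0, v0, h)
    pr <- projected_transfer_magnitude(st)
    expect_lt(abs(pr$magnitude - closed_form_magnitude(st)), 1e-12)
    expect_identical(pr$fp_component + pr$v_component, pr$magnitude)
    expect_gte(pr$fp_coefficient, 1)
    expect_gte(pr$v_coefficient, 0)
    expect_lte(abs(pr$magnitude), abs(x0))
  }
})

test_that("projection is conserved along passive trajectories", {
  # the magnitude is a function of the orbital energy only, so every
  # point of a passive trajectory before the stationary time projects
  # to the same minimum
  st <- pendulum_state(-0.15, 0.25, 0.95)
  t_star <- stationary_time(st)$t_star
  ref <- projected_transfer_magnitude(st)$magnitude
  for (t in seq(0, 0.95 * t_star, length.out = 20)) {
    x_t <- lipm_trajectory(st, t)
    v_t <- comtransfer:::lipm_velocity(st, t)
    m_t <- projected_transfer_magnitude(
      pendulum_state(x_t, v_t, st$height))$magnitude
    expect_lt(abs(m_t - ref), 1e-9)
  }
})

test_that("projected magnitude is monotone in velocity and placement", {
  w <- sqrt(9.81)
  v_grid <- seq(0, 0.9 * w * 0.10, length.out = 25)
  mags <- vapply(v_grid, function(v) {
    projected_transfer_magnitude(pendulum_state(-0.10, v, 1.0))$magnitude
  }, 0)
  expect_true(all(diff(mags) > 0))  # faster approach: closer to pivot
  x_grid <- seq(-0.05, -0.25, length.out = 25)
  mags2 <- vapply(x_grid, function(x) {
    projected_transfer_magnitude(pendulum_state(x, 0.1, 1.0))$magnitude
  }, 0)
  expect_true(all(diff(mags2) < 0))  # wider placement: further away
})
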