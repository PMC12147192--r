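test_that("stance frame sign convention is mirror symmetric", {
  # right stance: CoM 8 cm left of the right foot, moving rightward
  tr_r <- make_linear_trial(com0 = 0.02 - 0.12, com_v = 0.12)
  st_r <- stance_frame(tr_r, "right", 1.0)
  expect_equal(st_r$x0, -0.08, tolerance = 1e-6)
  expect_equal(st_r$v0, 0.12, tolerance = 1e-6)
  expect_false(st_r$lateral)
  # left stance: CoM 8 cm right of the left foot, moving leftward
  tr_l <- make_linear_trial(com0 = -0.02 + 0.12, com_v = -0.12)
  st_l <- stance_frame(tr_l, "left", 1.0)
  expect_equal(st_l$x0, -0.08, tolerance = 1e-6)
  expect_equal(st_l$v0, 0.12, tolerance = 1e-6)
  # CoM lateral to the pivot is flagged, not an error
  tr_x <- make_linear_trial(com0 = 0.15, com_v = 0)
  expect_true(stance_frame(tr_x, "right", 1.0)$lateral)
})

test_that("passive step projection is conserved from contact to completion", {
  # exact closed-form samples, no filtering: the projection from any
  # instant equals the realised minimum to sampling precision
  trial <- make_passive_step_trial(x0 = -0.12, v0 = 0.20, kin_rate = 500)
  st0 <- pendulum_state(-0.12, 0.20, 1.0)
  expected <- projected_transfer_magnitude(st0)$magnitude
  step <- list(leading_side = "right", t_ic = 0.002, t_cfo = 0.1,
               t_next_ic = 0.45)
  pr <- step_projections(trial, step)
  expect_lt(abs(pr$proj_ic - expected), 1e-4)
  expect_lt(abs(pr$proj_cfo - expected), 1e-4)
  expect_lt(abs(pr$proj_ic - pr$proj_cfo), 1e-5)
  fin <- final_transfer_magnitude(trial, step)
  expect_lt(abs(fin - expected), 1e-5)
  # decomposition identity carried through the pipeline
  expect_identical(pr$fp_component + pr$v_component, pr$proj_ic)
})

test_that("trailing limb work is exact for constant force and velocity", {
  # right-leading step: trailing belt is the left; constant 5 N and
  # 0.1 m/s give F*v*T exactly under trapezoidal quadrature
  trial <- make_linear_trial(com0 = -0.1, com_v = 0.1, grfL_x = 5)
  trial <- preprocess_trial(trial)
  step <- list(leading_side = "right", t_ic = 0.50, t_cfo = 0.80)
  wk <- trailing_limb_work(trial, step)
  expect_equal(wk$work_ds, 5 * 0.1 * 0.3, tolerance = 1e-3)
  expect_equal(wk$avg_power_ds, 0.5, tolerance = 1e-3)
  expect_equal(wk$avg_mlgrf_ds, 5, tolerance = 1e-3)
  expect_equal(wk$avg_vel_ds, 0.1, tolerance = 1e-3)
  # zero trailing force: zero work
  trial0 <- preprocess_trial(make_linear_trial(grfL_x = 0))
  wk0 <- trailing_limb_work(trial0, step)
  expect_lt(abs(wk0$work_ds), 1e-9)
  # sub-3-sample window is flagged
  wk_short <- trailing_limb_work(trial, list(leading_side = "right",
                                             t_ic = 0.5, t_cfo = 0.501))
  expect_equal(wk_short$flag, "short_window")
})

test_that("work recovery and telescoping hold on generator trials", {
  sim <- simulate_trial(synthetic_config(n_steps = 10, seed = 2,
                                         noise_pos_sd = 0, noise_grf_sd = 0))
  m <- compute_step_metrics(preprocess_trial(sim$trial))
  inc <- m[!m$excluded, ]
  tru <- sim$truth
  idx <- vapply(inc$t_ic, function(t) which.min(abs(tru$t_ic - t)), 0L)
  rel <- abs(inc$work_ds - tru$work_ds[idx]) / abs(tru$work_ds[idx])
  expect_lt(max(rel), 0.02)
  # telescoping identity is exact by construction, for every step
  expect_lt(max(abs(inc$proj_ic + inc$delta_ds + inc$delta_ess -
                      inc$final_mag)), 1e-15)
  expect_true(all(inc$ess_duration > 0))
  expect_true(all(inc$final_mag < 0))
})

test_that("double-support change tracks injected work across steps", {
  # work varies step to step; placement and velocity noise are off, so
  # the work input should explain nearly all of the double-support
  # change in the projection
  cfg <- synthetic_config(n_steps = 20, seed = 6, noise_pos_sd = 0,
                          noise_grf_sd = 0, fp_sd_p = 0, fp_sd_np = 0,
                          v_ic_sd = 0, work_sd = 0.8)
  sim <- simulate_trial(cfg)
  m <- compute_step_metrics(preprocess_trial(sim$trial))
  rg <- work_vs_delta_regression(m)
  expect_gt(rg$paretic$r_squared, 0.95)
  expect_gt(rg$non_paretic$r_squared, 0.95)
  expect_gt(rg$paretic$slope, 0)
})
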