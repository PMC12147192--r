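fake_steps <- function(p_final, np_final, p_ic = p_final, np_ic = np_final,
                       p_cfo = p_final, np_cfo = np_final,
                       work = NULL) {
  n_p <- length(p_final); n_np <- length(np_final)
  tibble::tibble(
    transfer_direction = c(rep("paretic", n_p), rep("non_paretic", n_np)),
    excluded = FALSE,
    proj_ic = c(p_ic, np_ic),
    proj_cfo = c(p_cfo, np_cfo),
    final_mag = c(p_final, np_final),
    delta_ds = proj_cfo - proj_ic,
    delta_ess = final_mag - proj_cfo,
    work_ds = if (is.null(work)) stats::runif(n_p + n_np, 1, 3) else work)
}

test_that("asymmetry follows the non-paretic-minus-paretic sign rule", {
  steps <- fake_steps(p_final = rep(-0.12, 5), np_final = rep(-0.08, 5))
  a <- asymmetry_evolution(steps)
  expect_equal(a$asym_final, 0.04)   # positive: greater non-paretic transfer
  expect_equal(a$flag, "ok")
  few <- fake_steps(p_final = rep(-0.1, 2), np_final = rep(-0.1, 5))
  expect_equal(asymmetry_evolution(few)$flag, "insufficient_data")
})

test_that("phase contributions telescope to 100 percent", {
  expect_equal(unlist(phase_contributions(0.03, 0.03, 0.03)[1:3]),
               c(contrib_ic = 100, contrib_ds = 0, contrib_ess = 0))
  pc <- phase_contributions(0.54 * 0.05, 0.92 * 0.05, 0.05)
  expect_equal(pc$contrib_ic, 54)
  expect_equal(pc$contrib_ds, 38, tolerance = 1e-9)
  expect_equal(pc$contrib_ess, 8, tolerance = 1e-9)
  set.seed(3)
  for (i in 1:20) {
    v <- stats::rnorm(3, 0.03, 0.02)
    if (abs(v[3]) < 1e-6) next
    pc <- phase_contributions(v[1], v[2], v[3])
    expect_equal(pc$contrib_ic + pc$contrib_ds + pc$contrib_ess, 100,
                 tolerance = 1e-9)
  }
  expect_equal(phase_contributions(0.01, 0.01, 1e-8)$flag, "undefined")
})

test_that("prediction MAE is zero for a perfect projection", {
  steps <- fake_steps(p_final = seq(-0.12, -0.10, length.out = 5),
                      np_final = seq(-0.09, -0.07, length.out = 5))
  mae <- cfo_prediction_mae(steps)
  expect_equal(mae$mae_p, 0)
  expect_equal(mae$mae_np, 0)
  steps$proj_cfo <- steps$final_mag + 0.002
  expect_equal(cfo_prediction_mae(steps)$mae_p, 0.002)
})

test_that("perfect compensation gives a control correlation of -1", {
  set.seed(8)
  p_ic <- stats::rnorm(12, -0.13, 0.01)
  np_ic <- stats::rnorm(12, -0.11, 0.01)
  target <- -0.10
  steps <- fake_steps(p_final = rep(target, 12), np_final = rep(target, 12),
                      p_ic = p_ic, np_ic = np_ic,
                      p_cfo = rep(target, 12), np_cfo = rep(target, 12))
  rr <- stepwise_control_correlation(steps)
  expect_equal(rr$r_p, -1, tolerance = 1e-6)
  expect_equal(rr$r_np, -1, tolerance = 1e-6)
  # degenerate: no variance in either variable
  flat <- fake_steps(p_final = rep(-0.1, 6), np_final = rep(-0.1, 6))
  expect_true(is.na(stepwise_control_correlation(flat)$r_p))
})

test_that("variability SDs behave and compensation shrinks them", {
  flat <- fake_steps(p_final = rep(-0.1, 6), np_final = rep(-0.1, 6))
  sds <- transfer_variability(flat)
  expect_equal(sds$sd_ic_p, 0)
  expect_equal(sds$sd_final_np, 0)
  # generator with a gain-1 controller: the double-support adjustment
  # absorbs placement variability, so final SD falls well below IC SD
  sim <- simulate_trial(synthetic_config(
    n_steps = 14, seed = 5, compensation_gain = 1,
    target_magnitude = -0.12, work_sd = 0,
    noise_pos_sd = 0, noise_grf_sd = 0))
  m <- compute_step_metrics(preprocess_trial(sim$trial))
  sds2 <- transfer_variability(m)
  expect_lt(sds2$sd_final_p, 0.5 * sds2$sd_ic_p)
  expect_lt(sds2$sd_final_np, 0.5 * sds2$sd_ic_np)
})

test_that("work regression recovers an exact linear relation", {
  work <- seq(1, 3, length.out = 8)
  steps <- fake_steps(p_final = rep(-0.1, 8), np_final = rep(-0.1, 8),
                      p_ic = rep(-0.12, 8), np_ic = rep(-0.12, 8),
                      p_cfo = -0.12 + 0.01 * work,
                      np_cfo = -0.12 + 0.01 * work,
                      work = c(work, work))
  # lm warns about the (intentionally) perfect fit
  rg <- suppressWarnings(work_vs_delta_regression(steps))
  expect_equal(rg$paretic$r_squared, 1, tolerance = 1e-12)
  expect_equal(rg$paretic$slope, 0.01, tolerance = 1e-12)
  novar <- fake_steps(p_final = rep(-0.1, 8), np_final = rep(-0.1, 8),
                      work = rep(2, 16))
  expect_true(is.na(work_vs_delta_regression(novar)$paretic$r_squared))
})

test_that("trade-off calculators reproduce their closed forms", {
  expect_equal(velocity_offset_for_fp(0, 1.05, 0.10), 0)
  expect_equal(round(velocity_offset_for_fp(0.01, 1.05, 0.10), 3), 0.105)
  expect_equal(velocity_offset_for_fp(0.02, 1.05, 0.10),
               2 * velocity_offset_for_fp(0.01, 1.05, 0.10))
  expect_error(velocity_offset_for_fp(0.01, 1.05, 0), "positive")
  expect_equal(round(fp_share_of_final_asymmetry(53.9, 10), 1), 49.0)
  expect_equal(fp_share_of_final_asymmetry(53.9, 1e9), 53.9,
               tolerance = 1e-6)
  expect_equal(fp_share_of_final_asymmetry(40, 1), 20)
})

test_that("participant summary assembles a coherent outcome row", {
  sim <- simulate_trial(synthetic_config(n_steps = 16, seed = 13))
  m <- compute_step_metrics(preprocess_trial(sim$trial))
  s <- participant_summary(m, "S13")
  expect_equal(s$participant_id, "S13")
  expect_equal(s$contrib_ic + s$contrib_ds + s$contrib_ess, 100,
               tolerance = 1e-9)
  expect_gte(s$mae_p, 0)
  expect_true(abs(s$r_np) <= 1)
  expect_equal(s$n_steps_p + s$n_steps_np, sum(!m$excluded))
  expect_equal(s$asym_final,
               s$final_mag_np - s$final_mag_p, tolerance = 1e-12)
})

test_that("analyze_cohort stacks participants and writes tidy tables", {
  cohort <- simulate_cohort(n_participants = 2,
                            config = synthetic_config(n_steps = 8),
                            seed = 3)
  out_dir <- withr::local_tempdir()
  res <- analyze_cohort(cohort$trials, out_dir = out_dir)
  expect_equal(nrow(res$participants), 2)
  expect_true(all(c("asym_ic", "contrib_ic", "mae_p", "sd_final_np")
                  %in% names(res$participants)))
  expect_true(file.exists(file.path(out_dir, "participant_summary.tsv")))
  expect_true(file.exists(file.path(out_dir, "steps.tsv")))
  expect_true(file.exists(file.path(out_dir, "step_metrics.tsv")))
  expect_true(file.exists(file.path(out_dir, "cohort_summary.json")))
  js <- jsonlite::read_json(file.path(out_dir, "cohort_summary.json"))
  expect_equal(js$n_participants, 2)
})
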