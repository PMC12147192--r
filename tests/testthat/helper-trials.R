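# Hand-built miniature trials with analytically known content.

# CoM translating at constant mediolateral velocity between two fixed
# feet; optionally a constant mediolateral force on one belt.
make_linear_trial <- function(duration = 2, kin_rate = 100,
                              kinet_rate = 1000,
                              com0 = 0.02, com_v = 0.12,
                              lfoot = -0.10, rfoot = 0.10,
                              grfL_x = 0, grfR_x = 0,
                              body_mass = 75) {
  kt <- seq(0, duration, by = 1 / kin_rate)
  qt <- seq(0, duration, by = 1 / kinet_rate)
  n <- length(kt); q <- length(qt)
  kin <- tibble::tibble(
    time_s = kt,
    com_x = com0 + com_v * kt, com_y = 0, com_z = 1.0,
    lfoot_x = lfoot, lfoot_y = 0, lfoot_z = 0,
    rfoot_x = rfoot, rfoot_y = 0, rfoot_z = 0)
  mg2 <- body_mass * 9.81 / 2
  kinet <- tibble::tibble(
    time_s = qt,
    grfL_x = grfL_x, grfL_y = 0, grfL_z = mg2,
    grfR_x = grfR_x, grfR_y = 0, grfR_z = mg2)
  gait_trial(kin, kinet,
             meta = list(participant_id = "T", paretic_side = "left",
                         body_mass_kg = body_mass, body_height_m = 1.7,
                         kin_rate_hz = kin_rate, kinet_rate_hz = kinet_rate,
                         belt_midline_x_m = 0))
}

# single passive pendulum step sampled directly from the closed-form
# trajectory (no filtering required: mark as preprocessed by hand so
# the metric layer sees the exact samples)
make_passive_step_trial <- function(x0 = -0.12, v0 = 0.20, height = 1.0,
                                    kin_rate = 500, duration = 0.5,
                                    foot = 0.10) {
  st <- pendulum_state(x0, v0, height)
  kt <- seq(0, duration, by = 1 / kin_rate)
  com <- foot + lipm_trajectory(st, kt)          # right stance frame
  kin <- tibble::tibble(
    time_s = kt, com_x = com, com_y = 0, com_z = height,
    lfoot_x = -0.10, lfoot_y = 0, lfoot_z = 0,
    rfoot_x = foot, rfoot_y = 0, rfoot_z = 0)
  qt <- seq(0, duration, by = 1 / 1000)
  kinet <- tibble::tibble(time_s = qt, grfL_x = 0, grfL_y = 0, grfL_z = 0,
                          grfR_x = 0, grfR_y = 0, grfR_z = 735)
  trial <- gait_trial(kin, kinet,
                      meta = list(participant_id = "P", paretic_side = "left",
                                  body_mass_kg = 75, body_height_m = 1.7,
                                  kin_rate_hz = kin_rate, kinet_rate_hz = 1000,
                                  belt_midline_x_m = 0))
  trial$kin$com_vx <- differentiate(trial$kin$com_x, kin_rate)
  trial$kinet$com_vx <- sample_at(trial$kin$com_vx, trial$kin$time_s,
                                  pmin(qt, max(kt)))
  trial$prepped <- TRUE
  trial
}

# small, fast generator configuration used across tests
quick_config <- function(...) {
  synthetic_config(n_steps = 8, ...)
}
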