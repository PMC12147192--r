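# Synthetic treadmill gait-trial generator with exact analytic ground
# truth. Stance-phase mediolateral CoM motion follows LIPM dynamics:
# passive during single support, with a half-sine trailing-limb force
# per unit mass during double support. Both regimes have closed-form
# solutions (the forced equation x'' = w^2 x + a*sin(Om*t) has the
# particular solution -a*sin(Om*t)/(w^2 + Om^2)), so trajectories,
# event times and injected work are exact, not integrated numerically.

#' Configuration for the synthetic gait-trial generator
#'
#' Defaults emulate slow post-stroke treadmill walking: CoM height
#' 1.0 m, mediolateral CoM velocity at initial contact around
#' 0.15 m/s, foot placement around 15 cm (non-paretic) and 17 cm
#' (paretic; a 2 cm widening), trailing-limb double-support work input
#' around 3.5 J for non-paretic transfers and about 30% less for paretic
#' transfers, 1 mm kinematic and 2 N kinetic measurement noise, and
#' 100 / 1000 Hz sampling. Step timing emerges from the pendulum
#' dynamics; `step_period` is nominal and, together with
#' `ds_fraction`, fixes only the double-support duration.
#'
#' Work injection has two modes: fixed per-side targets
#' (`work_target_p` / `work_target_np`, used when `compensation_gain`
#' is `NULL`) or a step-to-step compensation controller that chooses
#' each step's work so the projected magnitude moves a fraction
#' `compensation_gain` of the way from its initial-contact value to
#' `target_magnitude`. Gaussian work noise `work_sd` applies in both
#' modes.
#'
#' @param n_steps Number of complete steps with ground truth.
#' @param com_height Constant CoM height (m).
#' @param step_period Nominal step period (s).
#' @param ds_fraction Double-support fraction of the nominal period
#'   (0-0.5); `ds_duration = ds_fraction * step_period`.
#' @param fp_mean_p,fp_mean_np,fp_sd_p,fp_sd_np Side-specific foot
#'   placement distributions (m; paretic / non-paretic transfers).
#' @param v_ic_mean,v_ic_sd CoM approach velocity at initial contact
#'   (m/s).
#' @param work_target_p,work_target_np Trailing-limb double-support
#'   work targets (J) for paretic / non-paretic transfers.
#' @param work_sd Step-to-step work variability (J).
#' @param centring_gain Foot-placement correction gain for slow
#'   mediolateral drift relative to the belt midline (dimensionless;
#'   0 disables this channel of lateral position control).
#' @param v_centring_gain Approach-velocity correction gain for the
#'   same drift (1/s; the velocity channel is the effective lever,
#'   since under passive pendulum dynamics a wider placement deepens
#'   the fall-back almost exactly and barely shifts the net
#'   displacement).
#' @param compensation_gain Optional controller gain (dimensionless).
#' @param target_magnitude Controller target projected magnitude
#'   (m, negative); required with `compensation_gain`.
#' @param body_mass Body mass (kg).
#' @param body_height Body height (m), metadata only.
#' @param noise_pos_sd Additive Gaussian noise on kinematic channels
#'   (m).
#' @param noise_grf_sd Additive Gaussian noise on kinetic channels (N).
#' @param kin_rate,kinet_rate Sampling rates (Hz).
#' @param paretic_side `"left"` or `"right"`.
#' @param participant_id Identifier written to metadata.
#' @param belt_midline_x Belt midline position (m).
#' @param seed RNG seed; the same seed reproduces the trial bit for
#'   bit.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_steps = 30,
                             com_height = 1.0,
                             step_period = 0.7,
                             ds_fraction = 0.285,
                             fp_mean_p = 0.17, fp_mean_np = 0.15,
                             fp_sd_p = 0.012, fp_sd_np = 0.010,
                             v_ic_mean = 0.15, v_ic_sd = 0.015,
                             work_target_p = 2.5, work_target_np = 3.5,
                             work_sd = 0.3,
                             centring_gain = 0.3,
                             v_centring_gain = 1.2,
                             compensation_gain = NULL,
                             target_magnitude = NULL,
                             body_mass = 75, body_height = 1.70,
                             noise_pos_sd = 0.001, noise_grf_sd = 2,
                             kin_rate = 100, kinet_rate = 1000,
                             paretic_side = "left",
                             participant_id = "S01",
                             belt_midline_x = 0,
                             seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_steps >= 1, cfg$com_height > 0,
            cfg$ds_fraction > 0, cfg$ds_fraction < 0.5,
            cfg$fp_sd_p >= 0, cfg$fp_sd_np >= 0, cfg$v_ic_sd >= 0,
            cfg$work_sd >= 0, cfg$body_mass > 0,
            cfg$noise_pos_sd >= 0, cfg$noise_grf_sd >= 0,
            cfg$kin_rate > 0, cfg$kinet_rate >= cfg$kin_rate,
            cfg$paretic_side %in% c("left", "right"))
  if (!is.null(cfg$compensation_gain) && is.null(cfg$target_magnitude)) {
    stop("`target_magnitude` is required with `compensation_gain`.",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# End state of the forced double-support segment
# x'' = w^2 x + a sin(Om t), t in [0, T], Om = pi/T, from (x0, v0).
ds_end_state <- function(x0, v0, a, w, T_ds) {
  Om <- pi / T_ds
  k <- a / (w^2 + Om^2)
  A <- x0
  B <- (v0 + k * Om) / w
  ch <- cosh(w * T_ds); sh <- sinh(w * T_ds)
  list(x = A * ch + B * sh,            # sin(pi) = 0
       v = w * (A * sh + B * ch) + k * Om,  # cos(pi) = -1
       A = A, B = B, k = k, Om = Om)
}

# Per-unit-mass work injected over the segment equals the orbital
# energy change E = (v^2 - w^2 x^2)/2; exactly quadratic in `a`.
ds_work <- function(x0, v0, a, w, T_ds) {
  e0 <- (v0^2 - w^2 * x0^2) / 2
  s <- ds_end_state(x0, v0, a, w, T_ds)
  (s$v^2 - w^2 * s$x^2) / 2 - e0
}

# Forcing amplitude that injects a prescribed per-unit-mass work.
solve_amplitude <- function(x0, v0, w, T_ds, w_target) {
  c1 <- (ds_work(x0, v0, 1, w, T_ds) - ds_work(x0, v0, -1, w, T_ds)) / 2
  c2 <- (ds_work(x0, v0, 1, w, T_ds) + ds_work(x0, v0, -1, w, T_ds)) / 2
  if (abs(c2) < 1e-14) return(w_target / c1)
  disc <- c1^2 + 4 * c2 * w_target
  if (disc < 0) return(NA_real_)
  (-c1 + sqrt(disc)) / (2 * c2)
}

smoothstep <- function(s) {
  s <- pmin(1, pmax(0, s))
  s * s * (3 - 2 * s)
}

#' Simulate one synthetic gait trial
#'
#' Generates a multi-step treadmill walking trial whose mediolateral
#' CoM motion obeys LIPM stance dynamics with prescribed half-sine
#' trailing-limb force injection during double support, side-specific
#' foot placement and velocity draws, trapezoidal vertical load
#' transfer, smooth foot swing trajectories, and additive measurement
#' noise, together with the exact ground truth of every step. Step
#' draws that would fall over the pivot are redrawn up to 10 times.
#'
#' @param config A [synthetic_config()].
#' @return List with `trial` (a [gait_trial()]) and `truth` (tibble of
#'   per-step ground truth: event times, foot placement, velocity,
#'   projected magnitudes, final magnitude, injected work).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  w <- sqrt(GRAVITY / cfg$com_height)
  T_ds <- cfg$ds_fraction * cfg$step_period
  mass <- cfg$body_mass
  n_total <- cfg$n_steps + 1L   # last step has no following contact

  sides <- rep(c("left", "right"), length.out = n_total + 1L)
  # virtual step 0 establishes the opening single support
  side0 <- sides[1]
  sides <- sides[-1]
  dir_of <- function(s) if (s == cfg$paretic_side) "paretic" else "non_paretic"
  fp_mean <- function(s) if (dir_of(s) == "paretic") cfg$fp_mean_p else cfg$fp_mean_np
  fp_sd <- function(s) if (dir_of(s) == "paretic") cfg$fp_sd_p else cfg$fp_sd_np
  work_mu <- function(s) if (dir_of(s) == "paretic") cfg$work_target_p else cfg$work_target_np
  sgn <- function(s) if (s == "right") 1 else -1

  # Steady-state treadmill walking requires zero net mediolateral CoM
  # displacement per left-right stride. With independent per-side foot
  # placement and work levels the balance is achieved through the
  # approach velocity: solve for the side split of the mean IC
  # velocity that equalises the two steps' net displacements
  # |FP - D_exit|, where D_exit^2 = FP^2 - (v_in^2 - v_out^2)/w^2 -
  # 2 W/(m w^2) is the CoM-pivot distance when the next contact
  # occurs. (Compensatory velocity asymmetry, not a measurement
  # artefact.)
  v_split <- if (is.null(cfg$compensation_gain)) {
    fpp <- cfg$fp_mean_p; fpn <- cfg$fp_mean_np
    wp <- cfg$work_target_p / mass; wn <- cfg$work_target_np / mass
    net_gap <- function(d) {
      vp <- cfg$v_ic_mean + d; vn <- cfg$v_ic_mean - d
      dp2 <- fpp^2 - (vp^2 - vn^2) / w^2 - 2 * wp / w^2
      dn2 <- fpn^2 - (vn^2 - vp^2) / w^2 - 2 * wn / w^2
      if (dp2 <= 0 || dn2 <= 0) return(NA_real_)
      (fpp - sqrt(dp2)) - (fpn - sqrt(dn2))
    }
    dd <- seq(-0.08, 0.08, by = 0.002)
    gg <- vapply(dd, net_gap, 0)
    okd <- which(is.finite(gg))
    root <- tryCatch({
      sgn_change <- which(diff(sign(gg[okd])) != 0)
      if (!length(sgn_change)) 0 else
        stats::uniroot(net_gap, c(dd[okd[sgn_change[1]]],
                                  dd[okd[sgn_change[1] + 1]]))$root
    }, error = function(e) 0)
    root
  } else 0
  v_mean_side <- function(s) {
    if (dir_of(s) == "paretic") cfg$v_ic_mean + v_split
    else cfg$v_ic_mean - v_split
  }
  draw_v <- function(s) max(0.03, stats::rnorm(1, v_mean_side(s),
                                               cfg$v_ic_sd))

  # opening stance: completion state of a virtual prior step at t = 0
  fp0 <- fp_mean(side0)
  m0 <- -sqrt(max(fp0^2 - (cfg$v_ic_mean / w)^2, 1e-4))
  foot0_x <- -sgn(side0) * m0
  v_next <- draw_v(sides[1])
  t_ic <- asinh(v_next / (w * abs(m0))) / w

  steps <- vector("list", n_total)
  com_at <- foot0_x + sgn(side0) * m0 * cosh(w * t_ic)
  for (i in seq_len(n_total)) {
    s <- sides[i]
    sg <- sgn(s)
    v_i <- v_next
    # weak lateral position control: foot placement corrects slow
    # mediolateral drift of the CoM relative to the belt midline, as
    # treadmill walkers do; zero-mean once the walker is centred
    centring <- max(-0.025, min(0.025,
      cfg$centring_gain * sg * (cfg$belt_midline_x - com_at)))
    ok <- FALSE
    for (attempt in 1:10) {
      fp_i <- max(0.04, stats::rnorm(1, fp_mean(s), fp_sd(s)) + centring)
      if (v_i / (w * fp_i) >= 0.97) next
      proj_ic <- -sqrt(fp_i^2 - (v_i / w)^2)
      if (!is.null(cfg$compensation_gain)) {
        m_des <- proj_ic + cfg$compensation_gain *
          (cfg$target_magnitude - proj_ic)
        w_t <- mass * w^2 * (proj_ic^2 - m_des^2) / 2 +
          stats::rnorm(1, 0, cfg$work_sd)
      } else {
        w_t <- stats::rnorm(1, work_mu(s), cfg$work_sd)
      }
      a <- solve_amplitude(-fp_i, v_i, w, T_ds, w_t / mass)
      if (is.na(a)) next
      end <- ds_end_state(-fp_i, v_i, a, w, T_ds)
      if (end$x >= -1e-3 || end$v <= 1e-3) next
      if (end$v / (w * abs(end$x)) >= 0.985) next
      # approach must persist throughout double support
      tau <- seq(0, T_ds, length.out = 41)
      xs <- end$A * cosh(w * tau) + end$B * sinh(w * tau) -
        end$k * sin(end$Om * tau)
      vs <- w * (end$A * sinh(w * tau) + end$B * cosh(w * tau)) -
        end$k * end$Om * cos(end$Om * tau)
      if (any(xs >= 0) || any(vs <= 0)) next
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("Could not draw a dynamically valid step after 10 attempts; ",
           "check the configuration.", call. = FALSE)
    }
    foot_x <- com_at + sg * fp_i  # foot lateral to the CoM
    u_cfo <- end$v / (w * abs(end$x))
    t_star <- atanh(u_cfo) / w
    m_fin <- -sqrt(end$x^2 - (end$v / w)^2)
    side_next <- if (i < n_total) sides[i + 1] else
      if (s == "left") "right" else "left"
    # velocity channel of lateral position control: raising the
    # approach speed at one side's contacts shifts the CoM towards
    # that side over the stride
    com_pred <- foot_x + sg * m_fin
    dv <- cfg$v_centring_gain * (-sg) * (cfg$belt_midline_x - com_pred)
    dv <- max(-0.03, min(0.03, dv))
    v_next <- max(0.03, draw_v(side_next) + dv)
    tau_fb <- asinh(v_next / (w * abs(m_fin))) / w
    steps[[i]] <- list(
      side = s, sgn = sg, t_ic = t_ic, t_cfo = t_ic + T_ds,
      t_completion = t_ic + T_ds + t_star,
      t_next_ic = t_ic + T_ds + t_star + tau_fb,
      fp = fp_i, v_ic = v_i, proj_ic = proj_ic,
      proj_cfo = m_fin, final_mag = m_fin, work = w_t,
      a = a, A = end$A, B = end$B, k = end$k, Om = end$Om,
      x_cfo = end$x, v_cfo = end$v, foot_x = foot_x)
    com_at <- foot_x + sg * (m_fin * cosh(w * tau_fb))
    t_ic <- steps[[i]]$t_next_ic
  }
  t_end <- steps[[n_total]]$t_cfo + 0.05

  frame_x <- function(tv) {
    out <- numeric(length(tv))
    pre <- tv < steps[[1]]$t_ic
    out[pre] <- foot0_x + sgn(side0) * m0 * cosh(w * tv[pre])
    for (i in seq_len(n_total)) {
      st <- steps[[i]]
      hi <- if (i < n_total) steps[[i + 1]]$t_ic else t_end + 1e-9
      ds <- tv >= st$t_ic & tv < st$t_cfo
      ss <- tv >= st$t_cfo & tv < hi
      if (any(ds)) {
        tau <- tv[ds] - st$t_ic
        out[ds] <- st$foot_x + st$sgn *
          (st$A * cosh(w * tau) + st$B * sinh(w * tau) -
             st$k * sin(st$Om * tau))
      }
      if (any(ss)) {
        tau <- tv[ss] - st$t_cfo
        out[ss] <- st$foot_x + st$sgn *
          (st$x_cfo * cosh(w * tau) + (st$v_cfo / w) * sinh(w * tau))
      }
    }
    out
  }

  # per-belt channels -------------------------------------------------
  belt_steps <- function(side) {
    idx <- which(vapply(steps, function(s) s$side, "") == side)
    if (side == side0) {
      c(list(list(side = side0, sgn = sgn(side0), t_ic = 0,
                  foot_x = foot0_x, virtual = TRUE)),
        lapply(idx, function(i) steps[[i]]))
    } else {
      lapply(idx, function(i) steps[[i]])
    }
  }

  eval_belt <- function(side, tv) {
    bs <- belt_steps(side)
    fz <- numeric(length(tv)); fx <- numeric(length(tv))
    foot_pos <- rep(NA_real_, length(tv)); foot_z <- numeric(length(tv))
    mg <- mass * GRAVITY
    taper <- 0.06
    for (j in seq_along(bs)) {
      st <- bs[[j]]
      virt <- isTRUE(st$virtual)
      # this belt is in contact from its IC to the CFO of the next
      # (contralateral) step
      nxt <- Filter(function(o) o$t_ic > st$t_ic + 1e-12, steps)
      nxt <- if (length(nxt)) nxt[[1]] else NULL
      t_on <- st$t_ic
      t_off <- if (is.null(nxt)) t_end else nxt$t_cfo
      in_contact <- tv >= t_on & tv <= t_off
      foot_pos[in_contact] <- st$foot_x
      # vertical: ramp up over own DS, plateau, ramp down over next DS
      if (any(in_contact)) {
        tt <- tv[in_contact]
        up <- if (virt) rep(1, length(tt)) else
          pmin(1, (tt - t_on) / T_ds)
        down <- if (is.null(nxt)) rep(1, length(tt)) else
          pmin(1, pmax(0, (t_off - tt) / T_ds))
        fz[in_contact] <- mg * pmin(up, down)
        # mediolateral: pendulum line of action while leading/stance,
        # tapered out before the contralateral contact, then the
        # half-sine trailing-limb forcing of the next step
        x_fr <- st$sgn * (frame_x(tt) - st$foot_x)
        ml <- mass * st$sgn * w^2 * x_fr
        if (!is.null(nxt)) {
          tp0 <- nxt$t_ic - taper
          fade <- rep(1, length(tt))
          in_tp <- tt >= tp0 & tt < nxt$t_ic
          fade[in_tp] <- cos(0.5 * pi * (tt[in_tp] - tp0) / taper)^2
          fade[tt >= nxt$t_ic] <- 0
          ml <- ml * fade
          trail <- tt >= nxt$t_ic & tt <= nxt$t_cfo
          ml[trail] <- mass * nxt$sgn * nxt$a *
            sin(nxt$Om * (tt[trail] - nxt$t_ic))
        }
        fx[in_contact] <- ml
      }
      # swing to the next same-side placement
      nxt_same <- Filter(function(o) o$t_ic > st$t_ic + 1e-12 &&
                           o$side == side, steps)
      if (length(nxt_same)) {
        tgt <- nxt_same[[1]]
        sw <- tv > t_off & tv < tgt$t_ic
        if (any(sw)) {
          sfrac <- (tv[sw] - t_off) / (tgt$t_ic - t_off)
          foot_pos[sw] <- st$foot_x +
            (tgt$foot_x - st$foot_x) * smoothstep(sfrac)
          foot_z[sw] <- 0.05 * sin(pi * sfrac)
        }
      } else {
        foot_pos[tv > t_off] <- st$foot_x
      }
    }
    # before the first contact of this belt the foot rests at its
    # upcoming placement
    first_on <- bs[[1]]$t_ic
    foot_pos[tv < first_on] <- bs[[1]]$foot_x
    list(fz = fz, fx = fx, foot_x = foot_pos, foot_z = foot_z)
  }

  kin_t <- seq(0, t_end, by = 1 / cfg$kin_rate)
  kinet_t <- seq(0, t_end, by = 1 / cfg$kinet_rate)
  left_kin <- eval_belt("left", kin_t)
  right_kin <- eval_belt("right", kin_t)
  left_kinet <- eval_belt("left", kinet_t)
  right_kinet <- eval_belt("right", kinet_t)

  npos <- function(n) stats::rnorm(n, 0, cfg$noise_pos_sd)
  ngrf <- function(n) stats::rnorm(n, 0, cfg$noise_grf_sd)
  nk <- length(kin_t); nq <- length(kinet_t)
  kin <- tibble::tibble(
    time_s = kin_t,
    com_x = frame_x(kin_t) + npos(nk),
    com_y = npos(nk),
    com_z = cfg$com_height + npos(nk),
    lfoot_x = left_kin$foot_x + npos(nk),
    lfoot_y = npos(nk),
    lfoot_z = left_kin$foot_z + npos(nk),
    rfoot_x = right_kin$foot_x + npos(nk),
    rfoot_y = npos(nk),
    rfoot_z = right_kin$foot_z + npos(nk))
  kinet <- tibble::tibble(
    time_s = kinet_t,
    grfL_x = left_kinet$fx + ngrf(nq),
    grfL_y = ngrf(nq),
    grfL_z = pmax(0, left_kinet$fz) + ngrf(nq),
    grfR_x = right_kinet$fx + ngrf(nq),
    grfR_y = ngrf(nq),
    grfR_z = pmax(0, right_kinet$fz) + ngrf(nq))
  meta <- list(participant_id = cfg$participant_id,
               paretic_side = cfg$paretic_side,
               body_mass_kg = cfg$body_mass,
               body_height_m = cfg$body_height,
               kin_rate_hz = cfg$kin_rate,
               kinet_rate_hz = cfg$kinet_rate,
               belt_midline_x_m = cfg$belt_midline_x)
  trial <- gait_trial(kin, kinet, meta)

  keep <- seq_len(cfg$n_steps)
  truth <- tibble::tibble(
    step_index = keep,
    leading_side = vapply(steps[keep], function(s) s$side, ""),
    transfer_direction = vapply(steps[keep],
                                function(s) dir_of(s$side), ""),
    t_ic = vapply(steps[keep], function(s) s$t_ic, 0),
    t_cfo = vapply(steps[keep], function(s) s$t_cfo, 0),
    t_completion = vapply(steps[keep], function(s) s$t_completion, 0),
    t_next_ic = vapply(steps[keep], function(s) s$t_next_ic, 0),
    fp = vapply(steps[keep], function(s) s$fp, 0),
    v_ic = vapply(steps[keep], function(s) s$v_ic, 0),
    proj_ic = vapply(steps[keep], function(s) s$proj_ic, 0),
    proj_cfo = vapply(steps[keep], function(s) s$proj_cfo, 0),
    final_mag = vapply(steps[keep], function(s) s$final_mag, 0),
    work_ds = vapply(steps[keep], function(s) s$work, 0),
    x_cfo = vapply(steps[keep], function(s) s$x_cfo, 0),
    v_cfo = vapply(steps[keep], function(s) s$v_cfo, 0))
  list(trial = trial, truth = truth)
}

#' Simulate a synthetic cohort
#'
#' Draws per-participant configurations around a template (jittered
#' CoM height, body mass, foot placement, velocity and work levels,
#' randomized paretic side) with a prescribed paretic-side asymmetry,
#' simulates one trial per participant, and optionally writes the
#' trial bundles plus a stacked `ground_truth.tsv`.
#'
#' @param n_participants Number of participants.
#' @param config Template [synthetic_config()]; its non-paretic levels
#'   are the cohort base values.
#' @param asymmetry List with `fp_paretic_offset` (m, added to the
#'   paretic foot-placement mean; default 0.02) and
#'   `work_paretic_factor` (multiplier on the work injected during
#'   paretic transfers, i.e. by the non-paretic trailing limb; default
#'   0.7).
#' @param seed Cohort seed; participant seeds are derived from it.
#' @param dir Optional output directory for trial bundles and ground
#'   truth.
#' @return List with `trials`, `truths` (named by participant) and
#'   `configs`.
#' @export
simulate_cohort <- function(n_participants = 12,
                            config = synthetic_config(),
                            asymmetry = list(fp_paretic_offset = 0.02,
                                             work_paretic_factor = 0.7),
                            seed = 1, dir = NULL) {
  trials <- list(); truths <- list(); configs <- list()
  for (j in seq_len(n_participants)) {
    set.seed(seed * 1000L + j)
    pid <- sprintf("S%02d", j)
    cfg <- config
    cfg$participant_id <- pid
    cfg$seed <- seed * 1000L + 500L + j
    cfg$paretic_side <- sample(c("left", "right"), 1)
    cfg$com_height <- max(0.8, stats::rnorm(1, config$com_height, 0.04))
    cfg$body_mass <- max(45, stats::rnorm(1, config$body_mass, 8))
    fp_np <- max(0.08, stats::rnorm(1, config$fp_mean_np, 0.008))
    cfg$fp_mean_np <- fp_np
    cfg$fp_mean_p <- fp_np + (asymmetry$fp_paretic_offset %||% 0.02)
    cfg$v_ic_mean <- max(0.08, stats::rnorm(1, config$v_ic_mean, 0.012))
    w_np <- config$work_target_np * stats::runif(1, 0.85, 1.15)
    cfg$work_target_np <- w_np
    cfg$work_target_p <- w_np * (asymmetry$work_paretic_factor %||% 0.7)
    sim <- simulate_trial(cfg)
    trials[[pid]] <- sim$trial
    truths[[pid]] <- cbind(participant_id = pid, sim$truth)
    configs[[pid]] <- cfg
    if (!is.null(dir)) {
      write_trial(sim$trial, file.path(dir, pid))
    }
  }
  if (!is.null(dir)) {
    gt <- do.call(rbind, truths)
    utils::write.table(gt, file.path(dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(trials = trials, truths = truths, configs = configs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
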