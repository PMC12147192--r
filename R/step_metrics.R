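# Per-step scalars: foot placement, CoM velocity, projected transfer
# magnitudes at initial contact and contralateral foot off, final
# transfer magnitude, phase changes, and trailing-limb work input
# during double support.

side_sign <- function(leading_side) if (leading_side == "right") 1 else -1

#' Instantaneous pendulum state in the stance-foot frame
#'
#' Maps the lab-frame CoM and stance-foot trajectories into the
#' stance-foot frame at time `t`: `x0 = sigma * (com_x - foot_x)`,
#' `v0 = sigma * d(com_x)/dt`, where `sigma = +1` for right stance and
#' `-1` for left stance (lab +x is the participant's right). Under this
#' convention a medially located CoM gives `x0 < 0` and an approach
#' towards the pivot gives `v0 > 0` for either stance side. The
#' pendulum height is the instantaneous CoM height `com_z(t)`.
#'
#' @param trial Preprocessed [gait_trial()].
#' @param leading_side `"left"` or `"right"`.
#' @param t Evaluation time (s), within the kinematic range.
#' @return A [pendulum_state()].
#' @export
stance_frame <- function(trial, leading_side, t) {
  trial <- preprocess_trial(trial)
  kin <- trial$kin
  sgn <- side_sign(leading_side)
  foot_col <- if (leading_side == "right") "rfoot_x" else "lfoot_x"
  com_x <- sample_at(kin$com_x, kin$time_s, t)
  foot_x <- sample_at(kin[[foot_col]], kin$time_s, t)
  vx <- sample_at(kin$com_vx, kin$time_s, t)
  height <- sample_at(kin$com_z, kin$time_s, t)
  pendulum_state(x0 = sgn * (com_x - foot_x), v0 = sgn * vx,
                 height = height)
}

#' Projected transfer magnitudes of one step
#'
#' Builds the stance-foot-frame pendulum state at initial contact and
#' at contralateral foot off and applies
#' [projected_transfer_magnitude()] at each instant. The
#' foot-placement / velocity decomposition is retained from the
#' initial-contact state.
#'
#' @param trial Preprocessed [gait_trial()].
#' @param step One row of the [segment_steps()] table.
#' @return List with `proj_ic`, `proj_cfo` (signed m), `fp_ic`, `v_ic`,
#'   `fp_component`, `v_component`, `fp_coefficient`, `v_coefficient`,
#'   `status_ic`, `status_cfo`.
#' @export
step_projections <- function(trial, step) {
  st_ic <- stance_frame(trial, step$leading_side, step$t_ic)
  st_cfo <- stance_frame(trial, step$leading_side, step$t_cfo)
  pr_ic <- projected_transfer_magnitude(st_ic)
  pr_cfo <- projected_transfer_magnitude(st_cfo)
  list(proj_ic = pr_ic$magnitude, proj_cfo = pr_cfo$magnitude,
       fp_ic = st_ic$x0, v_ic = st_ic$v0,
       fp_component = pr_ic$fp_component, v_component = pr_ic$v_component,
       fp_coefficient = pr_ic$fp_coefficient,
       v_coefficient = pr_ic$v_coefficient,
       status_ic = pr_ic$status, status_cfo = pr_cfo$status)
}

#' Final CoM transfer magnitude of one step
#'
#' Signed mediolateral CoM--stance-foot distance at the transfer
#' completion instant (negative; the minimum distance reached during
#' single support).
#'
#' @param trial Preprocessed [gait_trial()].
#' @param step One row of the [segment_steps()] table with
#'   `t_completion` set.
#' @return Signed distance (m).
#' @export
final_transfer_magnitude <- function(trial, step) {
  comp <- find_transfer_completion(trial, step$leading_side,
                                   step$t_cfo, step$t_next_ic)
  comp$distance
}

#' Trailing-limb mechanical work input during double support
#'
#' Instantaneous trailing-limb power is the product of the trailing
#' belt's mediolateral ground reaction force and the mediolateral CoM
#' velocity, both mapped into the leading-stance sign convention
#' (`sigma = +1` right stance, `-1` left), so positive power pushes the
#' CoM towards the leading pivot on either side. Work is the
#' trapezoidal time integral of power over `[t_ic, t_cfo]` on the
#' kinetic timeline; the averages are time means over the same window.
#'
#' @param trial Preprocessed [gait_trial()].
#' @param step One row of the [segment_steps()] table.
#' @return List with `work_ds` (J), `avg_power_ds` (W),
#'   `avg_mlgrf_ds` (N), `avg_vel_ds` (m/s), `ds_duration` (s), and
#'   `flag` (`"ok"` or `"short_window"`).
#' @export
trailing_limb_work <- function(trial, step) {
  trial <- preprocess_trial(trial)
  kinet <- trial$kinet
  sgn <- side_sign(step$leading_side)
  trail_col <- if (step$leading_side == "right") "grfL_x" else "grfR_x"
  idx <- which(kinet$time_s >= step$t_ic & kinet$time_s <= step$t_cfo)
  if (length(idx) < 3L) {
    return(list(work_ds = NA_real_, avg_power_ds = NA_real_,
                avg_mlgrf_ds = NA_real_, avg_vel_ds = NA_real_,
                ds_duration = step$t_cfo - step$t_ic,
                flag = "short_window"))
  }
  tt <- kinet$time_s[idx]
  f <- sgn * kinet[[trail_col]][idx]
  v <- sgn * kinet$com_vx[idx]
  p <- f * v
  dur <- tt[length(tt)] - tt[1]
  work <- pracma::trapz(tt, p)
  list(work_ds = work,
       avg_power_ds = work / dur,
       avg_mlgrf_ds = pracma::trapz(tt, f) / dur,
       avg_vel_ds = pracma::trapz(tt, v) / dur,
       ds_duration = step$t_cfo - step$t_ic,
       flag = "ok")
}

#' Compute all per-step metrics of a trial
#'
#' Runs [step_projections()], [final_transfer_magnitude()] and
#' [trailing_limb_work()] on every non-excluded step and assembles the
#' per-step metric table. Steps whose pendulum state at initial contact
#' or contralateral foot off falls over the pivot are flagged
#' (`reason = "fall_over_pivot"`) and excluded. The phase changes are
#' defined by the telescoping decomposition
#' `final_mag = proj_ic + delta_ds + delta_ess` with
#' `delta_ds = proj_cfo - proj_ic` (double support) and
#' `delta_ess = final_mag - proj_cfo` (early single support).
#'
#' @param trial A [gait_trial()].
#' @param steps Optional step table from [segment_steps()]; segmented
#'   automatically when omitted.
#' @param threshold_n,min_duration_s Event-detection parameters used
#'   when `steps` is omitted.
#' @return Tibble with one row per step (excluded steps keep their
#'   exclusion flags and `NA` metrics).
#' @export
compute_step_metrics <- function(trial, steps = NULL, threshold_n = 20,
                                 min_duration_s = 0.05) {
  trial <- preprocess_trial(trial)
  if (is.null(steps)) {
    steps <- segment_steps(trial, threshold_n, min_duration_s)
  }
  metric_cols <- c("fp_ic", "v_ic", "proj_ic", "proj_cfo", "final_mag",
                   "delta_ds", "delta_ess", "work_ds", "avg_power_ds",
                   "avg_mlgrf_ds", "avg_vel_ds", "ds_duration",
                   "ess_duration", "fp_component", "v_component",
                   "fp_coefficient", "v_coefficient")
  out <- steps
  for (nm in metric_cols) out[[nm]] <- NA_real_
  for (k in seq_len(nrow(steps))) {
    if (steps$excluded[k]) next
    step <- steps[k, ]
    pr <- step_projections(trial, step)
    if (pr$status_ic == "fall_over_pivot" ||
        pr$status_cfo == "fall_over_pivot") {
      out$excluded[k] <- TRUE
      out$reason[k] <- "fall_over_pivot"
      next
    }
    fin <- final_transfer_magnitude(trial, step)
    wk <- trailing_limb_work(trial, step)
    if (wk$flag != "ok") {
      out$excluded[k] <- TRUE
      out$reason[k] <- wk$flag
      next
    }
    out$fp_ic[k] <- pr$fp_ic
    out$v_ic[k] <- pr$v_ic
    out$proj_ic[k] <- pr$proj_ic
    out$proj_cfo[k] <- pr$proj_cfo
    out$final_mag[k] <- fin
    out$delta_ds[k] <- pr$proj_cfo - pr$proj_ic
    out$delta_ess[k] <- fin - pr$proj_cfo
    out$work_ds[k] <- wk$work_ds
    out$avg_power_ds[k] <- wk$avg_power_ds
    out$avg_mlgrf_ds[k] <- wk$avg_mlgrf_ds
    out$avg_vel_ds[k] <- wk$avg_vel_ds
    out$ds_duration[k] <- wk$ds_duration
    out$ess_duration[k] <- step$t_completion - step$t_cfo
    out$fp_component[k] <- pr$fp_component
    out$v_component[k] <- pr$v_component
    out$fp_coefficient[k] <- pr$fp_coefficient
    out$v_coefficient[k] <- pr$v_coefficient
  }
  tibble::as_tibble(out)
}

#' Write the per-step metrics table
#'
#' @param metrics Table from [compute_step_metrics()].
#' @param participant_id Identifier prepended as a column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_step_metrics <- function(metrics, participant_id, path) {
  out <- cbind(participant_id = participant_id, metrics)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
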