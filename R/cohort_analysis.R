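# Participant-level outcomes: asymmetry evolution across gait events,
# phase contributions, prediction error, step-to-step control,
# variability, and the closed-form trade-off calculators.

included_by_side <- function(steps) {
  ok <- !steps$excluded & !is.na(steps$final_mag)
  split(steps[ok, ], steps$transfer_direction[ok])
}

side_means <- function(by_side, col) {
  c(p = mean(by_side$paretic[[col]]),
    np = mean(by_side$non_paretic[[col]]))
}

#' Asymmetry of CoM transfer magnitude at the three gait events
#'
#' Per-side means of the projected transfer magnitude at initial
#' contact and contralateral foot off and of the final transfer
#' magnitude, subtracted as non-paretic minus paretic. Since
#' magnitudes are negative with absolute value equal to the CoM--foot
#' distance, a positive asymmetry indicates a greater transfer towards
#' the non-paretic side.
#'
#' @param steps Per-step metric table from [compute_step_metrics()]
#'   (one participant).
#' @param min_steps Minimum included steps required per side
#'   (default 3).
#' @return List with `asym_ic`, `asym_cfo`, `asym_final` (m) and
#'   `flag` (`"ok"` or `"insufficient_data"`).
#' @export
asymmetry_evolution <- function(steps, min_steps = 3L) {
  by_side <- included_by_side(steps)
  if (length(by_side) < 2L || any(vapply(by_side, nrow, 0L) < min_steps)) {
    return(list(asym_ic = NA_real_, asym_cfo = NA_real_,
                asym_final = NA_real_, flag = "insufficient_data"))
  }
  a <- function(col) {
    m <- side_means(by_side, col)
    unname(m["np"] - m["p"])
  }
  list(asym_ic = a("proj_ic"), asym_cfo = a("proj_cfo"),
       asym_final = a("final_mag"), flag = "ok")
}

#' Phase contributions to the final transfer asymmetry
#'
#' The final asymmetry telescopes into the projected asymmetry at
#' initial contact plus its changes during double support and early
#' single support; each term expressed as a percentage of the final
#' asymmetry. The three contributions sum to 100% identically.
#'
#' @param asym_ic,asym_cfo,asym_final Asymmetries (m) from
#'   [asymmetry_evolution()].
#' @return List with `contrib_ic`, `contrib_ds`, `contrib_ess` (%),
#'   all `NA` with `flag = "undefined"` when `|asym_final| < 1e-6` m.
#' @export
phase_contributions <- function(asym_ic, asym_cfo, asym_final) {
  if (is.na(asym_final) || abs(asym_final) < 1e-6) {
    return(list(contrib_ic = NA_real_, contrib_ds = NA_real_,
                contrib_ess = NA_real_, flag = "undefined"))
  }
  list(contrib_ic = 100 * asym_ic / asym_final,
       contrib_ds = 100 * (asym_cfo - asym_ic) / asym_final,
       contrib_ess = 100 * (asym_final - asym_cfo) / asym_final,
       flag = "ok")
}

#' Mean absolute error of the foot-off prediction
#'
#' Per-side mean of `|proj_cfo - final_mag|`: how well the passive
#' pendulum projection from the contralateral-foot-off state predicts
#' the final transfer magnitude.
#'
#' @param steps Per-step metric table (one participant).
#' @return List with `mae_p`, `mae_np` (m).
#' @export
cfo_prediction_mae <- function(steps) {
  by_side <- included_by_side(steps)
  mae <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(NA_real_)
    mean(abs(df$proj_cfo - df$final_mag))
  }
  list(mae_p = mae(by_side$paretic), mae_np = mae(by_side$non_paretic))
}

#' Step-to-step control correlation
#'
#' Pearson correlation, across the steps of one side of one
#' participant, between the projected transfer magnitude at initial
#' contact and its change during double support. A negative r means
#' steps that start with a smaller projected transfer receive a larger
#' double-support adjustment.
#'
#' @param steps Per-step metric table (one participant).
#' @param min_steps Minimum included steps per side (default 5).
#' @return List with `r_p`, `r_np` (`NA` when undefined: too few steps
#'   or zero variance).
#' @export
stepwise_control_correlation <- function(steps, min_steps = 5L) {
  by_side <- included_by_side(steps)
  r_side <- function(df) {
    if (is.null(df) || nrow(df) < min_steps) return(NA_real_)
    if (stats::sd(df$proj_ic) == 0 || stats::sd(df$delta_ds) == 0) {
      return(NA_real_)
    }
    stats::cor(df$proj_ic, df$delta_ds)
  }
  list(r_p = r_side(by_side$paretic), r_np = r_side(by_side$non_paretic))
}

#' Step-to-step variability of the transfer magnitude
#'
#' Sample standard deviations (n - 1 denominator) across steps, per
#' side, of the projected transfer magnitude at initial contact and of
#' the final transfer magnitude.
#'
#' @param steps Per-step metric table (one participant).
#' @param min_steps Minimum included steps per side (default 3).
#' @return List with `sd_ic_p`, `sd_ic_np`, `sd_final_p`,
#'   `sd_final_np` (m).
#' @export
transfer_variability <- function(steps, min_steps = 3L) {
  by_side <- included_by_side(steps)
  sd_side <- function(df, col) {
    if (is.null(df) || nrow(df) < min_steps) return(NA_real_)
    stats::sd(df[[col]])
  }
  list(sd_ic_p = sd_side(by_side$paretic, "proj_ic"),
       sd_ic_np = sd_side(by_side$non_paretic, "proj_ic"),
       sd_final_p = sd_side(by_side$paretic, "final_mag"),
       sd_final_np = sd_side(by_side$non_paretic, "final_mag"))
}

#' Regression of the double-support change on trailing-limb work
#'
#' Per-side ordinary least squares of `delta_ds` (change in projected
#' transfer magnitude over double support, m) on `work_ds`
#' (trailing-limb work input, J): how much of the double-support
#' adjustment the kinetically derived work accounts for.
#'
#' @param steps Per-step metric table (one participant).
#' @param min_steps Minimum included steps per side (default 5).
#' @return List of two lists (`paretic`, `non_paretic`), each with
#'   `slope`, `intercept`, `r_squared` (`NA` when undefined).
#' @export
work_vs_delta_regression <- function(steps, min_steps = 5L) {
  by_side <- included_by_side(steps)
  fit_side <- function(df) {
    if (is.null(df) || nrow(df) < min_steps ||
        stats::sd(df$work_ds) == 0) {
      return(list(slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_))
    }
    fit <- stats::lm(delta_ds ~ work_ds, data = df)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared)
  }
  list(paretic = fit_side(by_side$paretic),
       non_paretic = fit_side(by_side$non_paretic))
}

#' CoM-velocity increase offsetting a foot-placement increase
#'
#' From the decomposition of the projected transfer magnitude, a
#' foot-placement widening of `delta_fp` changes the projection by
#' `-delta_fp * fp_coefficient`; the CoM-velocity increase whose
#' velocity-related component cancels it is
#' `delta_fp * fp_coefficient / v_coefficient`.
#'
#' @param delta_fp Foot-placement increase (m).
#' @param fp_coefficient Dimensionless foot-placement coefficient.
#' @param v_coefficient Velocity coefficient (s), > 0.
#' @return Required CoM-velocity increase (m/s).
#' @examples
#' velocity_offset_for_fp(0.01, 1.05, 0.10)
#' @export
velocity_offset_for_fp <- function(delta_fp, fp_coefficient,
                                   v_coefficient) {
  if (any(v_coefficient <= 0)) {
    stop("`v_coefficient` must be positive.", call. = FALSE)
  }
  delta_fp * fp_coefficient / v_coefficient
}

#' Foot-placement share of the final transfer asymmetry
#'
#' Scales the initial-contact contribution by the relative influence
#' of foot placement versus CoM velocity on the projection at initial
#' contact: with an influence ratio `rho` (foot placement about
#' `rho`-fold the velocity influence), the foot-placement share is
#' `contrib_ic * rho / (rho + 1)`.
#'
#' @param contrib_ic Initial-contact contribution (%).
#' @param influence_ratio Foot-placement-to-velocity influence ratio,
#'   > 0.
#' @return Foot-placement share (%).
#' @examples
#' fp_share_of_final_asymmetry(53.9, 10)
#' @export
fp_share_of_final_asymmetry <- function(contrib_ic, influence_ratio) {
  stopifnot(influence_ratio > 0)
  contrib_ic * influence_ratio / (influence_ratio + 1)
}

#' Summarise one participant's steps
#'
#' Assembles the full participant-level outcome row: per-side means of
#' every step metric, asymmetries at the three gait events, phase
#' contributions, prediction MAE, control correlations, variability
#' SDs and step counts.
#'
#' @param steps Per-step metric table from [compute_step_metrics()].
#' @param participant_id Identifier stored in the row.
#' @return One-row tibble (class `participant_summary` via its column
#'   set).
#' @export
participant_summary <- function(steps, participant_id = "P") {
  by_side <- included_by_side(steps)
  mean_cols <- c("proj_ic", "proj_cfo", "final_mag", "fp_ic", "v_ic",
                 "work_ds", "avg_power_ds", "avg_mlgrf_ds", "avg_vel_ds",
                 "ess_duration", "fp_coefficient", "v_coefficient")
  row <- list(participant_id = participant_id)
  for (col in mean_cols) {
    for (s in c("p", "np")) {
      df <- by_side[[if (s == "p") "paretic" else "non_paretic"]]
      row[[paste0(col, "_", s)]] <-
        if (is.null(df) || nrow(df) == 0L) NA_real_ else mean(df[[col]])
    }
  }
  asym <- asymmetry_evolution(steps)
  contrib <- phase_contributions(asym$asym_ic, asym$asym_cfo,
                                 asym$asym_final)
  mae <- cfo_prediction_mae(steps)
  rr <- stepwise_control_correlation(steps)
  sds <- transfer_variability(steps)
  row <- c(row, asym[c("asym_ic", "asym_cfo", "asym_final")],
           contrib[c("contrib_ic", "contrib_ds", "contrib_ess")],
           mae, rr, sds)
  row$n_steps_p <- if (is.null(by_side$paretic)) 0L else nrow(by_side$paretic)
  row$n_steps_np <- if (is.null(by_side$non_paretic)) 0L else
    nrow(by_side$non_paretic)
  row$flag <- asym$flag
  tibble::as_tibble(row)
}

#' Analyze a cohort of trials
#'
#' Runs the full pipeline (preprocess, segment, per-step metrics,
#' participant summary) over a set of trial bundles or in-memory
#' trials, and optionally writes the tidy output tables:
#' `steps.tsv` (events per step), `step_metrics.tsv`,
#' `participant_summary.tsv` and `cohort_summary.json`.
#'
#' @param trials Either a character vector of bundle path prefixes
#'   (see [read_trial()]) or a list of [gait_trial()] objects.
#' @param out_dir Optional output directory for the emitted tables.
#' @param threshold_n,min_duration_s Event-detection parameters.
#' @return List with `step_metrics` (all participants, stacked),
#'   `participants` (one row each) and `cohort` (grand means and SDs
#'   across participants).
#' @export
analyze_cohort <- function(trials, out_dir = NULL, threshold_n = 20,
                           min_duration_s = 0.05) {
  if (is.character(trials)) trials <- lapply(trials, read_trial)
  metrics_list <- vector("list", length(trials))
  summ_list <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- preprocess_trial(trials[[i]])
    pid <- tr$meta$participant_id
    m <- compute_step_metrics(tr, threshold_n = threshold_n,
                              min_duration_s = min_duration_s)
    metrics_list[[i]] <- cbind(participant_id = pid, m)
    summ_list[[i]] <- participant_summary(m, pid)
  }
  step_metrics <- tibble::as_tibble(do.call(rbind, metrics_list))
  participants <- tibble::as_tibble(do.call(rbind, summ_list))
  num_cols <- names(participants)[vapply(participants, is.numeric, TRUE)]
  cohort <- list(
    n_participants = nrow(participants),
    mean = lapply(participants[num_cols],
                  function(v) mean(v, na.rm = TRUE)),
    sd = lapply(participants[num_cols],
                function(v) stats::sd(v, na.rm = TRUE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    event_cols <- c("participant_id", "step_index", "leading_side",
                    "transfer_direction", "t_ic", "t_cfo", "t_completion",
                    "t_next_ic", "excluded", "reason")
    utils::write.table(step_metrics[, event_cols],
                       file.path(out_dir, "steps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(step_metrics, file.path(out_dir, "step_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(participants,
                       file.path(out_dir, "participant_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cohort, file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(step_metrics = step_metrics, participants = participants,
       cohort = cohort)
}
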