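# Gait event detection from kinetic data (initial contact,
# contralateral foot off), CoM transfer completion, step segmentation
# and exclusion rules.

# Run-length contact intervals of a thresholded vertical GRF signal,
# with a persistence ("debounce") requirement on both sides of each
# crossing. Crossing times are linearly interpolated between samples.
contact_intervals <- function(time_s, grf_z, threshold_n, min_duration_s) {
  above <- grf_z >= threshold_n
  if (!any(above)) {
    return(tibble::tibble(t_on = numeric(), t_off = numeric(),
                          onset_crossing = logical(),
                          offset_crossing = logical()))
  }
  r <- rle(above)
  len <- r$lengths
  ends <- cumsum(len)
  starts <- ends - len + 1L
  dt <- time_s[2] - time_s[1]
  min_n <- max(1L, as.integer(round(min_duration_s / dt)))
  # bridge sub-threshold dips shorter than the debounce window
  keep <- r$values | (len >= min_n)
  vals <- r$values
  vals[!keep] <- TRUE
  r2 <- rle(rep(vals, len))
  len <- r2$lengths
  ends <- cumsum(len)
  starts <- ends - len + 1L
  on_idx <- starts[r2$values]
  off_idx <- ends[r2$values]
  # drop supra-threshold bursts shorter than the debounce window
  ok <- (off_idx - on_idx + 1L) >= min_n
  on_idx <- on_idx[ok]
  off_idx <- off_idx[ok]
  cross_up <- function(i) {
    if (i == 1L) return(c(time_s[1], FALSE))
    t0 <- time_s[i - 1L]; y0 <- grf_z[i - 1L]; y1 <- grf_z[i]
    c(t0 + dt * (threshold_n - y0) / (y1 - y0), TRUE)
  }
  cross_down <- function(i) {
    if (i == length(time_s)) return(c(time_s[i], FALSE))
    t0 <- time_s[i]; y0 <- grf_z[i]; y1 <- grf_z[i + 1L]
    c(t0 + dt * (threshold_n - y0) / (y1 - y0), TRUE)
  }
  up <- t(vapply(on_idx, cross_up, numeric(2)))
  down <- t(vapply(off_idx, cross_down, numeric(2)))
  tibble::tibble(t_on = up[, 1], t_off = down[, 1],
                 onset_crossing = up[, 2] > 0,
                 offset_crossing = down[, 2] > 0)
}

#' Detect foot contact events from vertical ground reaction force
#'
#' Initial contact is the upward crossing of the filtered vertical GRF
#' of a belt through the threshold with at least `min_duration_s` of
#' supra-threshold persistence; foot off is the downward crossing with
#' the same sub-threshold persistence. Crossing times are linearly
#' interpolated between kinetic samples. Intervals that begin at the
#' first or end at the last sample carry no crossing
#' (`onset_crossing` / `offset_crossing` is `FALSE`) and are not usable
#' as events.
#'
#' @param trial A [gait_trial()] (preprocessed automatically if not
#'   already).
#' @param threshold_n Vertical force threshold (N), default 20.
#' @param min_duration_s Debounce persistence (s), default 0.05.
#' @return Tibble with `side`, `t_on`, `t_off`, `onset_crossing`,
#'   `offset_crossing`; empty (with a warning) when no crossings exist.
#' @export
detect_contact_events <- function(trial, threshold_n = 20,
                                  min_duration_s = 0.05) {
  trial <- preprocess_trial(trial)
  out <- lapply(c(left = "grfL_z", right = "grfR_z"), function(col) {
    contact_intervals(trial$kinet$time_s, trial$kinet[[col]],
                      threshold_n, min_duration_s)
  })
  out$left$side <- rep("left", nrow(out$left))
  out$right$side <- rep("right", nrow(out$right))
  res <- rbind(out$left, out$right)
  res <- res[order(res$t_on),
             c("side", "t_on", "t_off", "onset_crossing",
               "offset_crossing")]
  if (nrow(res) == 0L) {
    warning("No contact events found; check threshold and units.")
  }
  res
}

#' Find the CoM transfer completion instant of one step
#'
#' The completion of a CoM transfer is the time of minimum mediolateral
#' distance between the CoM and the ground projection of the stance
#' foot CoM during single support, searched over the kinematic samples
#' in `(t_cfo, t_next_ic)` and refined to sub-sample resolution by a
#' parabolic fit through the discrete minimum and its neighbours. A
#' minimum sitting on the window boundary (the CoM was already receding,
#' or still approaching at the next contact) is flagged.
#'
#' @param trial Preprocessed [gait_trial()].
#' @param leading_side `"left"` or `"right"` stance side of the step.
#' @param t_cfo,t_next_ic Single-support window bounds (s).
#' @return List with `time` (s), `distance` (signed m, negative),
#'   and `flag` (`"ok"`, `"boundary_minimum"` or `"incomplete"`).
#' @export
find_transfer_completion <- function(trial, leading_side, t_cfo, t_next_ic) {
  trial <- preprocess_trial(trial)
  kin <- trial$kin
  idx <- which(kin$time_s > t_cfo & kin$time_s < t_next_ic)
  if (length(idx) < 3L) {
    return(list(time = NA_real_, distance = NA_real_, flag = "incomplete"))
  }
  foot_col <- if (leading_side == "right") "rfoot_x" else "lfoot_x"
  sgn <- if (leading_side == "right") 1 else -1
  d_signed <- sgn * (kin$com_x[idx] - kin[[foot_col]][idx])
  d_abs <- abs(d_signed)
  i <- which.min(d_abs)
  if (i == 1L || i == length(idx)) {
    return(list(time = kin$time_s[idx[i]], distance = d_signed[i],
                flag = "boundary_minimum"))
  }
  # parabolic vertex through (i-1, i, i+1)
  h <- kin$time_s[2] - kin$time_s[1]
  y0 <- d_abs[i - 1L]; y1 <- d_abs[i]; y2 <- d_abs[i + 1L]
  denom <- y0 - 2 * y1 + y2
  off <- if (denom > 0) 0.5 * (y0 - y2) / denom else 0
  off <- max(-1, min(1, off))
  t_min <- kin$time_s[idx[i]] + off * h
  d_min <- y1 - 0.25 * (y0 - y2) * off
  list(time = t_min, distance = -d_min, flag = "ok")
}

annotation_overlap <- function(annotations, t0, t1) {
  if (nrow(annotations) == 0L) return(NA_character_)
  hit <- annotations$t_start < t1 & annotations$t_end > t0
  if (!any(hit)) return(NA_character_)
  annotations$label[which(hit)[1]]
}

#' Segment a trial into steps
#'
#' Pairs alternating initial contacts and foot offs into step segments
#' (one step = leading-limb initial contact to the contralateral
#' initial contact), locates the transfer completion within each
#' single-support window, assigns the transfer direction from the
#' leading side and the paretic side, and applies the exclusion rules:
#' overlap with a `handrail`/`crossover`/`toe_drag` annotation,
#' automatic crossover detection (leading foot placed across the belt
#' midline), boundary minima and incomplete windows.
#'
#' @param trial A [gait_trial()].
#' @param threshold_n Vertical GRF threshold (N) passed to
#'   [detect_contact_events()].
#' @param min_duration_s Debounce persistence (s).
#' @return Tibble of step segments: `step_index`, `leading_side`,
#'   `transfer_direction` (`"paretic"`/`"non_paretic"`), `t_ic`,
#'   `t_cfo`, `t_completion`, `t_next_ic`, `excluded`, `reason`.
#' @export
segment_steps <- function(trial, threshold_n = 20, min_duration_s = 0.05) {
  trial <- preprocess_trial(trial)
  ev <- detect_contact_events(trial, threshold_n, min_duration_s)
  ics <- ev[ev$onset_crossing, c("side", "t_on")]
  fos <- ev[ev$offset_crossing, c("side", "t_off")]
  if (nrow(ics) == 0L) {
    return(tibble::tibble(step_index = integer(), leading_side = character(),
                          transfer_direction = character(), t_ic = numeric(),
                          t_cfo = numeric(), t_completion = numeric(),
                          t_next_ic = numeric(), excluded = logical(),
                          reason = character()))
  }
  paretic <- trial$meta$paretic_side
  midline <- trial$meta$belt_midline_x_m
  rows <- vector("list", nrow(ics))
  for (k in seq_len(nrow(ics))) {
    side <- ics$side[k]
    other <- if (side == "left") "right" else "left"
    t_ic <- ics$t_on[k]
    cand_cfo <- fos$t_off[fos$side == other & fos$t_off > t_ic]
    cand_nic <- ics$t_on[ics$side == other & ics$t_on > t_ic]
    t_cfo <- if (length(cand_cfo)) min(cand_cfo) else NA_real_
    t_nic <- if (length(cand_nic)) min(cand_nic) else NA_real_
    excluded <- FALSE
    reason <- NA_character_
    t_comp <- NA_real_
    if (is.na(t_cfo) || is.na(t_nic) || !(t_ic < t_cfo && t_cfo < t_nic)) {
      excluded <- TRUE
      reason <- "incomplete"
    } else {
      ann <- annotation_overlap(trial$annotations, t_ic, t_nic)
      foot_col <- if (side == "right") "rfoot_x" else "lfoot_x"
      foot_ic <- sample_at(trial$kin[[foot_col]], trial$kin$time_s,
                           max(t_ic, trial$kin$time_s[1]))
      crossover <- if (side == "right") foot_ic < midline else foot_ic > midline
      comp <- find_transfer_completion(trial, side, t_cfo, t_nic)
      t_comp <- comp$time
      if (!is.na(ann)) {
        excluded <- TRUE; reason <- ann
      } else if (crossover) {
        excluded <- TRUE; reason <- "crossover"
      } else if (comp$flag != "ok") {
        excluded <- TRUE; reason <- comp$flag
      }
    }
    rows[[k]] <- tibble::tibble(
      leading_side = side,
      transfer_direction = if (side == paretic) "paretic" else "non_paretic",
      t_ic = t_ic, t_cfo = t_cfo, t_completion = t_comp, t_next_ic = t_nic,
      excluded = excluded, reason = reason)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$t_ic), ]
  tibble::as_tibble(cbind(step_index = seq_len(nrow(out)), out))
}

#' Write a per-step events table
#'
#' @param steps Step table from [segment_steps()].
#' @param participant_id Identifier prepended as a column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_steps <- function(steps, participant_id, path) {
  out <- cbind(participant_id = participant_id, steps)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
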