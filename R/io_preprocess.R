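# Trial container, trial-bundle IO, filtering, differentiation and
# kinematic/kinetic stream alignment.
#
# Coordinate convention: x = mediolateral (+ = participant's right),
# y = anterior-posterior, z = vertical (+ up), origin on the treadmill
# surface. SI units throughout (m, N, s, kg).

KIN_COLS <- c("time_s", "com_x", "com_y", "com_z",
              "lfoot_x", "lfoot_y", "lfoot_z",
              "rfoot_x", "rfoot_y", "rfoot_z")
KINET_COLS <- c("time_s", "grfL_x", "grfL_y", "grfL_z",
                "grfR_x", "grfR_y", "grfR_z")

check_uniform <- function(time_s, what) {
  if (length(time_s) < 2L || any(diff(time_s) <= 0)) {
    stop(sprintf("%s time vector must be strictly increasing.", what),
         call. = FALSE)
  }
  dt <- diff(time_s)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop(sprintf("%s time vector is not uniformly sampled.", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a gait trial
#'
#' Bundles the synchronized kinematic (CoM and foot-CoM trajectories)
#' and kinetic (per-belt ground reaction force) time series of one
#' treadmill walking trial, together with trial metadata and optional
#' exclusion annotations.
#'
#' @param kin Data frame with columns
#'   `time_s, com_x, com_y, com_z, lfoot_x, lfoot_y, lfoot_z,
#'   rfoot_x, rfoot_y, rfoot_z` (s and m), uniformly sampled.
#' @param kinet Data frame with columns
#'   `time_s, grfL_x, grfL_y, grfL_z, grfR_x, grfR_y, grfR_z` (s and N),
#'   uniformly sampled at a rate at least the kinematic rate.
#' @param meta List with `participant_id`, `paretic_side`
#'   (`"left"`/`"right"`), `body_mass_kg`, `body_height_m`,
#'   `kin_rate_hz`, `kinet_rate_hz`, `belt_midline_x_m`.
#' @param annotations Optional data frame with `t_start`, `t_end`,
#'   `label` (one of `"handrail"`, `"crossover"`, `"toe_drag"`); steps
#'   overlapping an annotated interval are excluded downstream.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(kin, kinet, meta, annotations = NULL) {
  kin <- tibble::as_tibble(kin)
  kinet <- tibble::as_tibble(kinet)
  if (!identical(names(kin), KIN_COLS)) {
    stop(sprintf("Kinematic table must have columns: %s",
                 paste(KIN_COLS, collapse = " ")), call. = FALSE)
  }
  if (!identical(names(kinet), KINET_COLS)) {
    stop(sprintf("Kinetic table must have columns: %s",
                 paste(KINET_COLS, collapse = " ")), call. = FALSE)
  }
  need <- c("participant_id", "paretic_side", "body_mass_kg",
            "body_height_m", "kin_rate_hz", "kinet_rate_hz",
            "belt_midline_x_m")
  missing_meta <- setdiff(need, names(meta))
  if (length(missing_meta)) {
    stop("Missing metadata fields: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  if (!meta$paretic_side %in% c("left", "right")) {
    stop("`paretic_side` must be \"left\" or \"right\".", call. = FALSE)
  }
  check_uniform(kin$time_s, "Kinematic")
  check_uniform(kinet$time_s, "Kinetic")
  if (meta$kinet_rate_hz < meta$kin_rate_hz) {
    stop("Kinetic rate must be >= kinematic rate.", call. = FALSE)
  }
  for (rate_chk in list(c("kin_rate_hz", 2L), c("kinet_rate_hz", 3L))) {
    tv <- if (rate_chk[[1]] == "kin_rate_hz") kin$time_s else kinet$time_s
    dt_obs <- stats::median(diff(tv))
    if (abs(dt_obs - 1 / meta[[rate_chk[[1]]]]) > 1e-6 * dt_obs) {
      stop(sprintf("Observed %s sampling interval does not match metadata.",
                   sub("_rate_hz", "ematic/etic", rate_chk[[1]])),
           call. = FALSE)
    }
  }
  # tolerate measurement noise around zero, flag gross sign/unit errors
  frac_neg <- function(v) mean(v < -5)
  if (min(kinet$grfL_z) < -50 || min(kinet$grfR_z) < -50 ||
      frac_neg(kinet$grfL_z) > 0.05 || frac_neg(kinet$grfR_z) > 0.05) {
    warning("Substantially negative vertical GRF found; ",
            "check belt assignment/units.")
  }
  if (is.null(annotations)) {
    annotations <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                                  label = character())
  } else {
    annotations <- tibble::as_tibble(annotations)
    stopifnot(all(c("t_start", "t_end", "label") %in% names(annotations)))
  }
  structure(list(kin = kin, kinet = kinet, meta = meta,
                 annotations = annotations),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> %s | paretic %s | %.0f kg | kin %d rows @ %g Hz | kinet %d rows @ %g Hz\n",
    x$meta$participant_id, x$meta$paretic_side, x$meta$body_mass_kg,
    nrow(x$kin), x$meta$kin_rate_hz, nrow(x$kinet), x$meta$kinet_rate_hz))
  invisible(x)
}

# Full-precision numeric formatting so that a write/read round trip is
# bit exact (17 significant digits round-trip an IEEE double).
format_full <- function(df) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  out
}

#' Write a gait trial bundle
#'
#' Writes `<prefix>.meta.json`, `<prefix>.kin.tsv` and
#' `<prefix>.kinet.tsv` (UTF-8, tab-delimited, `.` decimal). Numeric
#' samples are written with 17 significant digits, so
#' [read_trial()] reproduces them bit-exactly.
#'
#' @param trial A [gait_trial()].
#' @param prefix Path prefix of the bundle (no extension).
#' @return `prefix`, invisibly.
#' @export
write_trial <- function(trial, prefix) {
  stopifnot(inherits(trial, "gait_trial"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  meta <- trial$meta
  meta$annotations <- if (nrow(trial$annotations)) {
    lapply(seq_len(nrow(trial$annotations)), function(i) {
      as.list(trial$annotations[i, ])
    })
  } else list()
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(format_full(trial$kin), paste0(prefix, ".kin.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format_full(trial$kinet), paste0(prefix, ".kinet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a gait trial bundle
#'
#' Counterpart of [write_trial()]: reads and validates the three bundle
#' files under a path prefix.
#'
#' @param prefix Path prefix of the bundle (no extension).
#' @return A validated [gait_trial()].
#' @export
read_trial <- function(prefix) {
  paths <- paste0(prefix, c(".meta.json", ".kin.tsv", ".kinet.tsv"))
  ok <- file.exists(paths)
  if (!all(ok)) {
    stop("Missing trial bundle file(s): ",
         paste(paths[!ok], collapse = ", "), call. = FALSE)
  }
  meta <- jsonlite::read_json(paths[1], simplifyVector = FALSE)
  ann <- meta$annotations
  meta$annotations <- NULL
  meta <- lapply(meta, function(v) if (is.list(v)) unlist(v) else v)
  annotations <- if (length(ann)) {
    tibble::tibble(
      t_start = vapply(ann, function(a) as.numeric(a$t_start), 0),
      t_end = vapply(ann, function(a) as.numeric(a$t_end), 0),
      label = vapply(ann, function(a) as.character(a$label), ""))
  } else NULL
  kin <- tibble::as_tibble(utils::read.delim(paths[2], sep = "\t",
                                             check.names = FALSE))
  kinet <- tibble::as_tibble(utils::read.delim(paths[3], sep = "\t",
                                               check.names = FALSE))
  gait_trial(kin, kinet, meta, annotations)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order Butterworth design applied forward and backward
#' (zero phase, so event timing is not lag-shifted; the effective
#' magnitude response is squared). The signal is extended by odd
#' reflection at both ends before filtering to suppress edge
#' transients.
#'
#' @param x Uniformly sampled numeric signal.
#' @param cutoff Cutoff frequency (Hz); must be below Nyquist.
#' @param rate Sampling rate (Hz).
#' @param order Filter order of the one-pass design (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, cutoff, rate, order = 4) {
  if (cutoff >= rate / 2) {
    stop("`cutoff` must be below the Nyquist frequency rate/2.",
         call. = FALSE)
  }
  if (cutoff <= 0 || rate <= 0) {
    stop("`cutoff` and `rate` must be positive.", call. = FALSE)
  }
  n <- length(x)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # remove the endpoint-to-endpoint trend (restored afterwards) and
  # extend by odd reflection: together these suppress edge transients
  # and make the DC response exact
  trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1L) / (n - 1L)
  r <- x - trend
  npad <- min(n - 1L, as.integer(ceiling(3 * rate / cutoff)))
  if (npad < 1L) return(as.numeric(signal::filtfilt(bf, r)) + trend)
  head_pad <- 2 * r[1] - r[(npad + 1L):2L]
  tail_pad <- 2 * r[n] - r[(n - 1L):(n - npad)]
  y <- signal::filtfilt(bf, c(head_pad, r, tail_pad))
  y[(npad + 1L):(npad + n)] + trend
}

#' Numerical differentiation of a uniformly sampled series
#'
#' Central differences in the interior, one-sided differences at the
#' ends. Exact for linear signals.
#'
#' @param x Numeric series (>= 3 samples).
#' @param rate Sampling rate (Hz).
#' @return Derivative series, same length as `x`.
#' @export
differentiate <- function(x, rate) {
  n <- length(x)
  if (n < 3L) stop("Need at least 3 samples to differentiate.",
                   call. = FALSE)
  dt <- 1 / rate
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

#' Sample a series at arbitrary times by linear interpolation
#'
#' @param x Numeric series.
#' @param time_s Sample times of `x` (strictly increasing).
#' @param t_query Query time(s), within `range(time_s)`.
#' @return Interpolated value(s).
#' @export
sample_at <- function(x, time_s, t_query) {
  if (any(t_query < time_s[1]) || any(t_query > time_s[length(time_s)])) {
    stop("Query time outside the sampled range.", call. = FALSE)
  }
  stats::approx(time_s, x, xout = t_query, method = "linear")$y
}

#' Filter a trial and derive aligned CoM velocity
#'
#' Applies the package's preprocessing convention: zero-phase 4th-order
#' Butterworth low-pass filtering of all kinematic channels (default
#' cutoff 6 Hz) and kinetic channels (default 15 Hz), mediolateral CoM
#' velocity by central differences of the filtered position at the
#' kinematic rate, and the same velocity linearly interpolated onto the
#' kinetic timeline for power computation.
#'
#' @param trial A [gait_trial()].
#' @param kin_cutoff Kinematic low-pass cutoff (Hz), default 6.
#' @param kinet_cutoff Kinetic low-pass cutoff (Hz), default 15.
#' @return The trial with filtered tables in `$kin` / `$kinet`, CoM ML
#'   velocity columns `com_vx` on both timelines, and `$prepped = TRUE`.
#' @export
preprocess_trial <- function(trial, kin_cutoff = 6, kinet_cutoff = 15) {
  stopifnot(inherits(trial, "gait_trial"))
  if (isTRUE(trial$prepped)) return(trial)
  kin <- trial$kin
  kinet <- trial$kinet
  for (nm in setdiff(names(kin), "time_s")) {
    kin[[nm]] <- butterworth_lowpass(kin[[nm]], kin_cutoff,
                                     trial$meta$kin_rate_hz)
  }
  for (nm in setdiff(names(kinet), "time_s")) {
    kinet[[nm]] <- butterworth_lowpass(kinet[[nm]], kinet_cutoff,
                                       trial$meta$kinet_rate_hz)
  }
  kin$com_vx <- differentiate(kin$com_x, trial$meta$kin_rate_hz)
  kt <- kinet$time_s
  inside <- kt >= kin$time_s[1] & kt <= kin$time_s[nrow(kin)]
  vx <- rep(NA_real_, length(kt))
  vx[inside] <- sample_at(kin$com_vx, kin$time_s, kt[inside])
  kinet$com_vx <- vx
  trial$kin <- kin
  trial$kinet <- kinet
  trial$prepped <- TRUE
  trial
}
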