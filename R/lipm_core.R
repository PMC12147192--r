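# Closed-form linear inverted pendulum (LIPM) mathematics for the
# frontal plane: trajectory, stationary time, projected transfer
# magnitude and its foot-placement / velocity decomposition.

#' Gravitational acceleration used throughout the package (m/s^2)
#' @keywords internal
GRAVITY <- 9.81

#' LIPM eigenfrequency
#'
#' The time constant of the linear inverted pendulum,
#' \eqn{\omega = \sqrt{g / l}} with \eqn{g = 9.81} m/s\eqn{^2} and
#' \eqn{l} the (instantaneous) CoM height above the walking surface.
#'
#' @param height CoM height above the treadmill surface (m), > 0.
#' @return Eigenfrequency (1/s).
#' @examples
#' eigenfrequency(1.0)
#' @export
eigenfrequency <- function(height) {
  if (!is.numeric(height) || any(!is.finite(height)) || any(height <= 0)) {
    stop("`height` must be a positive, finite number (m).", call. = FALSE)
  }
  sqrt(GRAVITY / height)
}

#' Construct a frontal-plane pendulum state
#'
#' A pendulum state holds the mediolateral CoM position and velocity in
#' the stance-foot frame, where the pivot (stance-foot ground
#' projection) is the origin and the direction from the pivot towards
#' the CoM is negative. During a regular transfer `x0 < 0` (the CoM is
#' medial to the stance foot) and `v0 > 0` (the CoM approaches the
#' pivot).
#'
#' @param x0 Mediolateral CoM position relative to the pivot (m);
#'   negative on the medial side of the pivot.
#' @param v0 Mediolateral CoM velocity (m/s); positive towards the
#'   pivot.
#' @param height CoM height above the surface (m), > 0.
#' @return An object of class `pendulum_state` with fields `x0`, `v0`,
#'   `height`, `omega` and `lateral` (TRUE when `x0 >= 0`, i.e. the CoM
#'   is at or lateral to the pivot -- flagged, not an error).
#' @examples
#' pendulum_state(x0 = -0.10, v0 = 0.15, height = 1.0)
#' @export
pendulum_state <- function(x0, v0, height) {
  stopifnot(length(x0) == 1L, length(v0) == 1L, length(height) == 1L)
  if (!all(is.finite(c(x0, v0, height)))) {
    stop("Pendulum state components must be finite.", call. = FALSE)
  }
  omega <- eigenfrequency(height)
  structure(
    list(x0 = x0, v0 = v0, height = height, omega = omega,
         lateral = x0 >= 0),
    class = "pendulum_state"
  )
}

#' @export
print.pendulum_state <- function(x, ...) {
  cat(sprintf(
    "<pendulum_state> x0 = %.4f m, v0 = %.4f m/s, height = %.3f m, omega = %.4f 1/s%s\n",
    x$x0, x$v0, x$height, x$omega,
    if (isTRUE(x$lateral)) " [CoM lateral to pivot]" else ""))
  invisible(x)
}

#' Passive LIPM trajectory
#'
#' Mediolateral CoM position under passive pendulum dynamics
#' \eqn{\ddot x = \omega^2 x}, i.e.
#' \eqn{x(t) = x_0 \cosh(\omega t) + (\dot x_0/\omega)\sinh(\omega t)}.
#'
#' @param state A [pendulum_state()].
#' @param t Time(s) since the evaluation instant (s), >= 0. Vectorised.
#' @return Position(s) (m) in the stance-foot frame.
#' @examples
#' s <- pendulum_state(-0.10, 0, 1.0)
#' lipm_trajectory(s, c(0, 0.1, 0.2))
#' @export
lipm_trajectory <- function(state, t) {
  stopifnot(inherits(state, "pendulum_state"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be non-negative and finite.", call. = FALSE)
  }
  w <- state$omega
  state$x0 * cosh(w * t) + (state$v0 / w) * sinh(w * t)
}

# Velocity along the passive trajectory; internal helper.
lipm_velocity <- function(state, t) {
  w <- state$omega
  state$x0 * w * sinh(w * t) + state$v0 * cosh(w * t)
}

#' Time to the projected minimum CoM--pivot distance
#'
#' Setting the time derivative of the passive LIPM trajectory to zero
#' yields \eqn{\omega t^* = \mathrm{artanh}\!\big(\dot x_0/(\omega
#' |x_0|)\big)}. The solution exists only while the velocity-position
#' ratio \eqn{u = \dot x_0 / (\omega |x_0|)} lies in `[0, 1)`:
#'
#' * `0 <= u < 1`: status `"valid"`, `t_star` is the time of minimum
#'   distance (`t_star = 0` when `v0 = 0`: the CoM is at its minimum
#'   now).
#' * `v0 < 0`: status `"receding"` -- the CoM is moving away from the
#'   pivot, the minimum under passive dynamics is at (or before) the
#'   evaluation instant, and `t_star = 0`.
#' * `u >= 1`: status `"fall_over_pivot"` -- the pendulum would cross
#'   the pivot laterally and no minimum distance exists.
#'
#' @param state A [pendulum_state()] with `x0 != 0`.
#' @return A list with `t_star` (s, `NA` when falling over the pivot),
#'   `ratio` (dimensionless `u`) and `status`.
#' @examples
#' stationary_time(pendulum_state(-0.10, 0.15, 1.0))
#' @export
stationary_time <- function(state) {
  stopifnot(inherits(state, "pendulum_state"))
  if (state$x0 == 0) {
    stop("Degenerate state: x0 = 0 (CoM exactly over the pivot).",
         call. = FALSE)
  }
  w <- state$omega
  u <- state$v0 / (w * abs(state$x0))
  if (state$v0 < 0) {
    return(list(t_star = 0, ratio = u, status = "receding"))
  }
  if (u >= 1) {
    return(list(t_star = NA_real_, ratio = u, status = "fall_over_pivot"))
  }
  list(t_star = atanh(u) / w, ratio = u, status = "valid")
}

#' Projected CoM transfer magnitude and its decomposition
#'
#' Evaluates the passive trajectory at the stationary time to obtain
#' the projected minimum signed mediolateral CoM--pivot distance
#' (negative; its absolute value is the projected closest approach),
#' and splits it into a foot-placement-related and a velocity-related
#' component:
#' \deqn{M = \underbrace{x_0\cosh(\omega t^*)}_{\mathrm{FP}} +
#'       \underbrace{\dot x_0 \tfrac{1}{\omega}\sinh(\omega t^*)}_{\mathrm{CoM_v}}}
#' with coefficients \eqn{\cosh(\omega t^*) \ge 1} (dimensionless) and
#' \eqn{\sinh(\omega t^*)/\omega \ge 0} (s).
#'
#' When the CoM is receding (`v0 <= 0` ... strictly `v0 < 0`; `v0 = 0`
#' is the degenerate valid case with `t_star = 0`), the minimum under
#' passive dynamics is the current position, so `magnitude = x0` with
#' coefficients `(1, 0)`. When the state would fall over the pivot no
#' magnitude is defined and the fields are `NA`.
#'
#' @param state A [pendulum_state()].
#' @return An object of class `transfer_projection`: list with
#'   `magnitude`, `stationary_time`, `fp_component`, `v_component`,
#'   `fp_coefficient`, `v_coefficient`, `status`.
#' @examples
#' projected_transfer_magnitude(pendulum_state(-0.10, 0.15, 1.0))
#' @export
projected_transfer_magnitude <- function(state) {
  st <- stationary_time(state)
  w <- state$omega
  if (st$status == "fall_over_pivot") {
    out <- list(magnitude = NA_real_, stationary_time = NA_real_,
                fp_component = NA_real_, v_component = NA_real_,
                fp_coefficient = NA_real_, v_coefficient = NA_real_,
                status = "fall_over_pivot")
    return(structure(out, class = "transfer_projection"))
  }
  ts <- st$t_star
  cfp <- cosh(w * ts)
  cv <- sinh(w * ts) / w
  fp_comp <- state$x0 * cfp
  v_comp <- state$v0 * cv
  structure(
    list(magnitude = fp_comp + v_comp, stationary_time = ts,
         fp_component = fp_comp, v_component = v_comp,
         fp_coefficient = cfp, v_coefficient = cv,
         status = st$status),
    class = "transfer_projection"
  )
}

#' @export
print.transfer_projection <- function(x, ...) {
  cat(sprintf("<transfer_projection> status = %s\n", x$status))
  if (!is.na(x$magnitude)) {
    cat(sprintf("  magnitude     %.5f m  (at t* = %.4f s)\n",
                x$magnitude, x$stationary_time))
    cat(sprintf("  FP component  %.5f m  (coefficient %.4f)\n",
                x$fp_component, x$fp_coefficient))
    cat(sprintf("  v  component  %.5f m  (coefficient %.4f s)\n",
                x$v_component, x$v_coefficient))
  }
  invisible(x)
}

#' Closed-form projected transfer magnitude (orbital-energy oracle)
#'
#' Analytic simplification of the projected transfer magnitude:
#' substituting the stationary time into the passive trajectory gives
#' \eqn{M = -\sqrt{x_0^2 - (\dot x_0/\omega)^2}}, a function of the
#' conserved orbital energy \eqn{\dot x^2 - \omega^2 x^2} only. Used as
#' an independent check of [projected_transfer_magnitude()].
#'
#' @param state A [pendulum_state()] with `0 <= v0/(omega*|x0|) < 1`.
#' @return Projected minimum signed distance (m, negative).
#' @examples
#' closed_form_magnitude(pendulum_state(-0.10, 0.15, 1.0))
#' @export
closed_form_magnitude <- function(state) {
  stopifnot(inherits(state, "pendulum_state"))
  w <- state$omega
  u <- state$v0 / (w * abs(state$x0))
  if (state$v0 < 0 || u >= 1) {
    stop("closed_form_magnitude() requires 0 <= v0/(omega*|x0|) < 1.",
         call. = FALSE)
  }
  -sqrt(state$x0^2 - (state$v0 / w)^2)
}
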