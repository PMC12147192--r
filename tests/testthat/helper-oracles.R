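# Independent numerical oracles: Runge-Kutta integration of the
# pendulum equation x'' = w^2 x, kept deliberately separate from the
# closed forms they are used to check.

rk4_step <- function(x, v, w2, dt) {
  k1x <- v;                 k1v <- w2 * x
  k2x <- v + dt / 2 * k1v;  k2v <- w2 * (x + dt / 2 * k1x)
  k3x <- v + dt / 2 * k2v;  k3v <- w2 * (x + dt / 2 * k2x)
  k4x <- v + dt * k3v;      k4v <- w2 * (x + dt * k3x)
  list(x = x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x),
       v = v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v))
}

# trajectory positions at n*dt, n = 0..n_steps, for a single state
rk4_trajectory <- function(x0, v0, omega, dt, n_steps) {
  w2 <- omega^2
  out <- numeric(n_steps + 1)
  out[1] <- x0
  x <- x0; v <- v0
  for (i in seq_len(n_steps)) {
    s <- rk4_step(x, v, w2, dt)
    x <- s$x; v <- s$v
    out[i + 1] <- x
  }
  out
}

# minimum CoM-pivot distance (maximum of the negative x) along the
# passive trajectory, vectorised over states; integrates each state a
# little past its stationary time and records the grid maximum
rk4_min_distance <- function(x0, v0, omega, dt = 1e-5) {
  u <- v0 / (omega * abs(x0))
  t_stop <- atanh(pmin(u, 0.999)) / omega + 0.01
  x <- x0; v <- v0; w2 <- omega^2
  best <- x0
  active <- seq_along(x0)
  t_now <- 0
  block <- 2000L
  while (length(active)) {
    for (i in seq_len(block)) {
      s <- rk4_step(x, v, w2[active], dt)
      x <- s$x; v <- s$v
      best[active] <- pmax(best[active], x)
    }
    t_now <- t_now + block * dt
    keep <- t_stop[active] > t_now
    x <- x[keep]; v <- v[keep]
    active <- active[keep]
  }
  best
}
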