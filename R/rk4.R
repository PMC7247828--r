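#' One classical fourth-order Runge-Kutta step
#'
#' The same fixed-step update the learning architecture is templated on:
#' \eqn{k_1 = f(y)}, \eqn{k_2 = f(y + \Delta t k_1/2)},
#' \eqn{k_3 = f(y + \Delta t k_2/2)}, \eqn{k_4 = f(y + \Delta t k_3)},
#' \eqn{y_{next} = y + \Delta t (k_1 + 2k_2 + 2k_3 + k_4)/6}, with the same
#' `f` evaluated at all four stages.
#'
#' @param f vectorized function state -> time derivative.
#' @param y state value(s).
#' @param dt step size.
#' @return the advanced state(s).
#' @export
rk4_step <- function(f, y, dt) {
  k1 <- f(y)
  k2 <- f(y + dt / 2 * k1)
  k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
}

#' Fixed-step RK4 rollout over a time grid
#'
#' @inheritParams rk4_step
#' @param y0 initial state (scalar).
#' @param times increasing time grid; the state is reported at each entry.
#' @param h internal step size; each grid interval is subdivided into steps
#'   no longer than `h` (default: the grid spacing itself).
#' @return numeric vector of states at `times`.
#' @export
integrate_rk4 <- function(f, y0, times, h = NULL) {
  if (any(diff(times) <= 0)) stop_invalid("times must be increasing")
  out <- numeric(length(times))
  out[1] <- y <- y0
  for (i in seq_along(times)[-1]) {
    span <- times[i] - times[i - 1]
    nsub <- if (is.null(h)) 1L else max(1L, ceiling(span / h))
    hs <- span / nsub
    for (s in seq_len(nsub)) y <- rk4_step(f, y, hs)
    out[i] <- y
  }
  out
}
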