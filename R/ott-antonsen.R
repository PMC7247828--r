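#' Ott-Antonsen right-hand-side for the Kuramoto coherence
#'
#' In the continuum limit of the all-to-all Kuramoto model with Cauchy
#' distributed frequencies (scale `gamma`), the coherence obeys the closed
#' ODE \eqn{dR/dt = -\gamma R + (K/2) R (1 - R^2)} on the attracting
#' invariant manifold; the mean phase is stationary.
#'
#' @param r coherence value(s) in [0, 1] (values outside are accepted for
#'   evaluating learned models, but have no physical meaning).
#' @param k coupling constant.
#' @param gamma Cauchy scale parameter.
#' @return dR/dt, same length as `r`.
#' @examples
#' ott_antonsen_rhs(1, k = 2, gamma = 0.5) # -gamma
#' @export
ott_antonsen_rhs <- function(r, k = 2, gamma = 0.5) {
  -gamma * r + (k / 2) * r * (1 - r^2)
}

#' Stable fixed point of the Ott-Antonsen coherence dynamics
#'
#' For `k > 2 * gamma` the nonzero stable steady state is
#' \eqn{R_\infty = \sqrt{1 - 2\gamma/K}}; otherwise the incoherent state
#' R = 0 is the attractor and 0 is returned.
#'
#' @inheritParams ott_antonsen_rhs
#' @return the attracting steady-state coherence.
#' @export
ott_antonsen_fixed_point <- function(k = 2, gamma = 0.5) {
  if (k > 2 * gamma) sqrt(1 - 2 * gamma / k) else 0
}

#' Closed-form Ott-Antonsen coherence flow
#'
#' The coherence ODE is a Bernoulli equation: with \eqn{u = R^2},
#' \eqn{a = K/2 - \gamma}, \eqn{b = K/2}, the solution is the logistic flow
#' \eqn{u(t) = a u_0 e^{2at} / (a + b u_0 (e^{2at} - 1))}.
#'
#' @param r0 initial coherence.
#' @param t time(s) at which to evaluate the flow.
#' @inheritParams ott_antonsen_rhs
#' @return R(t), same length as `t`.
#' @export
ott_antonsen_flow <- function(r0, t, k = 2, gamma = 0.5) {
  a <- k / 2 - gamma
  b <- k / 2
  u0 <- r0^2
  if (abs(a) < 1e-14) return(sqrt(u0 / (1 + 2 * b * u0 * t)))
  e <- exp(2 * a * t)
  sqrt(a * u0 * e / (a + b * u0 * (e - 1)))
}

#' Time for the Ott-Antonsen flow to reach a target coherence
#'
#' Inverts the closed-form logistic flow. The target must lie strictly
#' between `r0` and the attracting value on the same side of the fixed
#' point; targets at or beyond the fixed point are unreachable in finite
#' time and return `Inf`.
#'
#' @param r0 initial coherence (> 0 for growth away from incoherence).
#' @param r_target target coherence.
#' @inheritParams ott_antonsen_rhs
#' @return the flow time t >= 0 (possibly `Inf`).
#' @export
ott_antonsen_time <- function(r0, r_target, k = 2, gamma = 0.5) {
  a <- k / 2 - gamma
  b <- k / 2
  u0 <- r0^2
  u <- r_target^2
  if (u == u0) return(0)
  num <- u * (a - b * u0)
  den <- u0 * (a - b * u)
  if (den == 0 || num / den <= 0) return(Inf)
  t <- log(num / den) / (2 * a)
  if (t < 0) Inf else t
}
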