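#' Kuramoto order parameter of a phase configuration
#'
#' Computes the complex mean phasor \eqn{R e^{i\psi} = (1/N)\sum_j
#' e^{i\theta_j}}: `R` is the phase coherence in [0, 1] and `psi` the mean
#' phase in (-pi, pi]. Both are invariant to a permutation of the
#' oscillators.
#'
#' @param theta numeric vector of phases, or a snapshots x N matrix.
#' @return for a vector, a list with `R` and `psi`; for a matrix, a
#'   data.frame with one row per snapshot.
#' @examples
#' order_parameter(c(0, pi / 2)) # R = sqrt(2)/2, psi = pi/4
#' @export
order_parameter <- function(theta) {
  if (is.matrix(theta)) {
    if (ncol(theta) == 0 || nrow(theta) == 0)
      stop_invalid("empty phase matrix")
    z_re <- rowMeans(cos(theta))
    z_im <- rowMeans(sin(theta))
    return(data.frame(R = sqrt(z_re^2 + z_im^2), psi = atan2(z_im, z_re)))
  }
  if (length(theta) == 0) stop_invalid("empty phase vector")
  z <- mean(complex(real = cos(theta), imaginary = sin(theta)))
  list(R = Mod(z), psi = Arg(z))
}

#' Order-parameter time series of a trajectory
#'
#' @param trajectory a `kuramoto_trajectory`.
#' @return data.frame with columns `time`, `R`, `psi`.
#' @export
order_parameter_series <- function(trajectory) {
  stopifnot(inherits(trajectory, "kuramoto_trajectory"))
  cbind(data.frame(time = trajectory$times),
        order_parameter(trajectory$phases))
}

#' Transform a trajectory into the co-rotating frame of the mean phase
#'
#' Applies \eqn{\theta_i(t) \mapsto \theta_i(t) - \psi(t)} snapshot by
#' snapshot, so the transformed mean phase is identically zero while the
#' coherence `R` of every snapshot is unchanged.
#'
#' @param trajectory a stationary-frame `kuramoto_trajectory`.
#' @return a `kuramoto_trajectory` with `frame = "rotating"`.
#' @export
to_rotating_frame <- function(trajectory) {
  stopifnot(inherits(trajectory, "kuramoto_trajectory"))
  op <- order_parameter(trajectory$phases)
  phases <- trajectory$phases - op$psi
  out <- trajectory
  out$phases <- phases
  out$frame <- "rotating"
  out
}

#' Histogram density of oscillator phases
#'
#' Phases are reduced modulo 2*pi into [-pi, pi) and binned on `n_bins`
#' equally spaced bins over [-pi, pi]. Both raw counts and the normalized
#' probability density (integrating to one over the circle) are returned.
#'
#' @param theta numeric vector of phases.
#' @param n_bins number of equal bins (default 200).
#' @return an object of class `phase_density` with `breaks` (n_bins + 1 bin
#'   edges), `counts`, `density` (counts / (N * bin width)), and `n`.
#' @export
phase_density <- function(theta, n_bins = 200) {
  if (n_bins < 1) stop_invalid("n_bins must be >= 1")
  if (length(theta) == 0) stop_invalid("empty phase vector")
  wrapped <- wrap_phase(theta)
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- findInterval(wrapped, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  width <- 2 * pi / n_bins
  structure(
    list(breaks = breaks, counts = counts,
         density = counts / (length(theta) * width), n = length(theta)),
    class = "phase_density")
}

#' @export
print.phase_density <- function(x, ...) {
  cat(sprintf("<phase_density: %d bins, N = %d>\n",
              length(x$counts), x$n))
  invisible(x)
}
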