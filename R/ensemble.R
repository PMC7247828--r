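#' Construct a Kuramoto-family oscillator ensemble
#'
#' An ensemble bundles the per-oscillator heterogeneities and the coupling
#' specification for one model instance. Four variants are recognized from
#' the fields supplied:
#' \describe{
#'   \item{`all2all`}{scalar coupling `k`: the classic mean-field model
#'     \eqn{d\theta_i/dt = \omega_i + (K/N)\sum_j \sin(\theta_j-\theta_i)}.}
#'   \item{`heterok`}{per-oscillator coupling vector `k`:
#'     \eqn{d\theta_i/dt = \omega_i + (K_i/N)\sum_j \sin(\theta_j-\theta_i)}.}
#'   \item{`firing`}{additionally an excitable "firing" term
#'     \eqn{\alpha_i \sin\theta_i} per oscillator.}
#'   \item{`network`}{a binary adjacency matrix `adjacency` with scalar `k`:
#'     \eqn{d\theta_i/dt = \omega_i + (K/N)\sum_j A_{ij}
#'     \sin(\theta_j-\theta_i)}.}
#' }
#'
#' @param omega numeric vector of natural frequencies (length N).
#' @param k coupling: a scalar (global K) or a length-N vector (per-oscillator
#'   K_i). With `adjacency` present, `k` must be scalar.
#' @param alpha optional per-oscillator firing coefficients (length N).
#' @param adjacency optional N x N symmetric 0/1 matrix with zero diagonal.
#' @return an object of class `oscillator_ensemble`.
#' @export
oscillator_ensemble <- function(omega, k, alpha = NULL, adjacency = NULL) {
  n <- length(omega)
  if (n < 1) stop_invalid("need at least one oscillator")
  if (!is.null(adjacency)) {
    if (length(k) != 1)
      stop_invalid(paste("an adjacency matrix requires a scalar coupling",
                         "constant; per-oscillator K_i with a network is",
                         "ambiguous"))
    if (!is.null(alpha))
      stop_invalid("the firing variant is defined for mean-field coupling")
    adjacency <- as.matrix(adjacency)
    if (!all(dim(adjacency) == n))
      stop_invalid("adjacency must be %d x %d", n, n)
    if (!isTRUE(all.equal(adjacency, t(adjacency))))
      stop_invalid("adjacency must be symmetric")
    if (any(diag(adjacency) != 0))
      stop_invalid("adjacency must have a zero diagonal")
    if (!all(adjacency %in% c(0, 1)))
      stop_invalid("adjacency entries must be 0 or 1")
  }
  if (!length(k) %in% c(1L, n))
    stop_invalid("k must be scalar or length N = %d", n)
  if (!is.null(alpha) && length(alpha) != n)
    stop_invalid("alpha must have length N = %d", n)
  variant <- if (!is.null(adjacency)) "network"
             else if (!is.null(alpha)) "firing"
             else if (length(k) == 1) "all2all" else "heterok"
  structure(
    list(omega = as.numeric(omega), k = as.numeric(k),
         alpha = if (!is.null(alpha)) as.numeric(alpha),
         adjacency = adjacency, n = n, variant = variant),
    class = "oscillator_ensemble")
}

#' @export
print.oscillator_ensemble <- function(x, ...) {
  cat(sprintf("<oscillator_ensemble: %s, N = %d>\n", x$variant, x$n))
  invisible(x)
}

# internal: map an ensemble onto the arguments of the compiled kernels
ensemble_cpp_args <- function(ensemble) {
  n <- ensemble$n
  variant_code <- switch(ensemble$variant,
                         all2all = 0L, heterok = 0L, firing = 1L,
                         network = 2L)
  list(variant = variant_code,
       omega = ensemble$omega,
       kvec = if (ensemble$variant %in% c("all2all", "heterok", "firing"))
                rep_len(ensemble$k, n) else numeric(n),
       alpha = ensemble$alpha %||% numeric(n),
       kglobal = if (ensemble$variant == "network") ensemble$k else 0,
       A = ensemble$adjacency %||% matrix(0, 0, 0))
}

#' Phase velocities of a Kuramoto-family ensemble
#'
#' Evaluates \eqn{d\theta_i/dt} for the ensemble's model variant. Mean-field
#' variants are computed through the O(N) order-parameter identity
#' \eqn{d\theta_i/dt = \omega_i + K_i R \sin(\psi - \theta_i)}; the network
#' variant uses the adjacency matrix-vector product. See
#' [kuramoto_rhs_pairwise()] for the O(N^2) pairwise sum, kept as an
#' independent cross-check.
#'
#' @param ensemble an [oscillator_ensemble()].
#' @param theta numeric vector of phases (length N).
#' @return numeric vector of phase velocities.
#' @export
kuramoto_rhs <- function(ensemble, theta) {
  stopifnot(inherits(ensemble, "oscillator_ensemble"))
  if (length(theta) != ensemble$n)
    stop_invalid("theta must have length N = %d", ensemble$n)
  n <- ensemble$n
  s <- sin(theta); cth <- cos(theta)
  if (ensemble$variant == "network") {
    As <- drop(ensemble$adjacency %*% s)
    Ac <- drop(ensemble$adjacency %*% cth)
    ensemble$omega + (ensemble$k / n) * (cth * As - s * Ac)
  } else {
    kvec <- rep_len(ensemble$k, n)
    S <- sum(s); C <- sum(cth)
    dth <- ensemble$omega + (kvec / n) * (S * cth - C * s)
    if (ensemble$variant == "firing") dth <- dth + ensemble$alpha * s
    dth
  }
}

#' Pairwise-sum phase velocities (O(N^2) reference implementation)
#'
#' Direct evaluation of the coupling sums without the mean-field identity.
#' Intended as a slow, independent oracle for validating [kuramoto_rhs()].
#'
#' @inheritParams kuramoto_rhs
#' @return numeric vector of phase velocities.
#' @export
kuramoto_rhs_pairwise <- function(ensemble, theta) {
  stopifnot(inherits(ensemble, "oscillator_ensemble"))
  n <- ensemble$n
  diff <- outer(theta, theta, function(ti, tj) sin(tj - ti))
  coupling <- if (ensemble$variant == "network") {
    (ensemble$k / n) * rowSums(ensemble$adjacency * diff)
  } else {
    rep_len(ensemble$k, n) / n * rowSums(diff)
  }
  dth <- ensemble$omega + coupling
  if (ensemble$variant == "firing") dth <- dth + ensemble$alpha * sin(theta)
  dth
}
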