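#' Steady-state phase dataset for effective-parameter discovery
#'
#' Simulates one of the heterogeneous Kuramoto variants to complete
#' synchronization, transforms to the rotating frame (so the mean phase is
#' zero), and embeds each oscillator's steady phase as a point on the unit
#' circle in the complex plane, \eqn{x_j = e^{i\theta_{j,\infty}}}. The
#' per-oscillator heterogeneities are recorded alongside so that a
#' discovered coordinate can be mapped back into parameter space.
#'
#' Default study conditions per variant:
#' \describe{
#'   \item{`heterok`}{N = 1500, frequencies uniform on [-pi, pi], coupling
#'     coefficients uniform on [10, 100].}
#'   \item{`firing`}{as `heterok` plus firing coefficients uniform on
#'     [-2, 2].}
#'   \item{`chung_lu`}{N = 4000, frequencies uniform on [0, 1], scalar
#'     coupling K = 20 on a Chung-Lu network with p = 0.5, q = 0.9,
#'     r = 0.5.}
#' }
#' All regimes synchronize completely, which the rotating-frame velocity
#' criterion verifies; an unmet criterion at `t_max` is an error.
#'
#' @param variant one of "heterok", "firing", "chung_lu".
#' @param n number of oscillators (variant default if NULL).
#' @param seed integer seed for heterogeneities, initial phases, and the
#'   network draw.
#' @param k coupling: range for the heterogeneous variants, scalar for the
#'   network variant (variant defaults if NULL).
#' @param omega_range,alpha_range heterogeneity ranges (variant defaults).
#' @param network optionally a prebuilt [chung_lu_network()] (lets several
#'   datasets share or vary the realization independently of `seed`).
#' @param vtol,t_max,chunk synchronization criterion and horizon, see
#'   [simulate_to_steady()]. The firing variant defaults to a tighter
#'   vtol = 1e-5: its steady balance divides by the firing coefficients,
#'   whose smallest draw amplifies any residual velocity.
#' @return an object of class `steady_state_dataset`: wrapped rotating-frame
#'   phases `theta`, unit-circle `embedding` (n x 2), coherence `R`, the
#'   residual `rotation` rate of the locked cluster, heterogeneity
#'   data.frame `het` (omega, k, alpha, kappa as applicable), `variant`,
#'   and the sync diagnostics.
#' @export
steady_state_dataset <- function(variant = c("heterok", "firing",
                                             "chung_lu"),
                                 n = NULL, seed = NULL, k = NULL,
                                 omega_range = NULL, alpha_range = c(-2, 2),
                                 network = NULL, vtol = NULL, t_max = 200,
                                 chunk = 5) {
  variant <- match.arg(variant)
  vtol <- vtol %||% (if (variant == "firing") 1e-5 else 1e-4)
  if (!is.null(seed)) set.seed(seed)
  if (variant == "chung_lu") {
    n <- n %||% 4000L
    k <- k %||% 20
    omega_range <- omega_range %||% c(0, 1)
    net <- network %||% chung_lu_network(n, p = 0.5, q = 0.9, r = 0.5)
    if (nrow(net$adjacency) != n)
      stop_invalid("network size does not match n")
    omega <- runif(n, omega_range[1], omega_range[2])
    ens <- oscillator_ensemble(omega, k = k, adjacency = net$adjacency)
    het <- data.frame(omega = omega, kappa = net$degrees)
  } else {
    n <- n %||% 1500L
    k <- k %||% c(10, 100)
    omega_range <- omega_range %||% c(-pi, pi)
    omega <- runif(n, omega_range[1], omega_range[2])
    ki <- runif(n, k[1], k[2])
    if (variant == "firing") {
      alpha <- runif(n, alpha_range[1], alpha_range[2])
      ens <- oscillator_ensemble(omega, k = ki, alpha = alpha)
      het <- data.frame(omega = omega, k = ki, alpha = alpha)
    } else {
      ens <- oscillator_ensemble(omega, k = ki)
      het <- data.frame(omega = omega, k = ki)
    }
  }
  theta0 <- runif(n, 0, 2 * pi)
  ss <- simulate_to_steady(ens, theta0, vtol = vtol, t_max = t_max,
                           chunk = chunk)
  op <- order_parameter(ss$theta)
  theta <- wrap_phase(ss$theta - op$psi)
  # Rotation rate of the locked cluster: zero in the continuum limit for
  # symmetric frequencies (and for the firing variant, whose steady state
  # is a true fixed point), but O(N^{-1/2}) for a finite sample. Steady
  # balances hold for the frame-relative frequencies omega - rotation.
  # `psi` is the steady state's own mean phase: physically meaningful for
  # the firing variant (the alpha*sin(theta) term pins the phase axis, so
  # zeroing psi by shifting phases is a relabeling of coordinates, not of
  # the state), arbitrary for the rotation-invariant variants.
  v <- kuramoto_rhs(ens, ss$theta)
  rotation <- mean(v)
  structure(
    list(theta = theta, psi = op$psi, embedding = cbind(cos(theta),
                                                        sin(theta)),
         R = op$R, rotation = rotation, het = het, variant = variant,
         ensemble = ens, sync = list(t = ss$t, vmax = ss$vmax)),
    class = "steady_state_dataset")
}

#' @export
print.steady_state_dataset <- function(x, ...) {
  cat(sprintf(
    "<steady_state_dataset: %s, N = %d, R = %.4f, synchronized at t = %g>\n",
    x$variant, length(x$theta), x$R, x$sync$t))
  invisible(x)
}

#' Discover effective parameters with an output-only informed kernel
#'
#' Runs the diffusion map on the unit-circle embedding of the steady-state
#' phases alone -- the oscillator heterogeneities never enter the kernel --
#' and selects the significant eigenfunctions by local linear regression.
#' Each significant eigenfunction is a data-driven "effective parameter":
#' a (possibly non-linear) combination of the original heterogeneities that
#' alone determines the steady-state phase. Eigenfunction values are
#' attached back to each oscillator's heterogeneity record.
#'
#' @param dataset a [steady_state_dataset()].
#' @param eps kernel bandwidth (default: median heuristic).
#' @param alpha normalization exponent (default 1).
#' @param n_eig number of non-trivial eigenpairs (default 10).
#' @param threshold LLR significance threshold (default 0.5).
#' @return a `dmap` object augmented with `residuals`, `significant`,
#'   `theta`, and `het` (heterogeneities plus a `phi1` column).
#' @export
output_only_effective_param <- function(dataset, eps = NULL, alpha = 1,
                                        n_eig = 10, threshold = 0.5) {
  stopifnot(inherits(dataset, "steady_state_dataset"))
  dm <- dmap(dataset$embedding, eps = eps, alpha = alpha, n_eig = n_eig,
             sign_ref = dataset$theta)
  dm$residuals <- llr_residuals(dm)
  dm$significant <- significant_of(dm, threshold)
  dm$theta <- dataset$theta
  dm$het <- cbind(dataset$het, phi1 = dm$eigenfunctions[, 1])
  dm
}

#' Analytic effective parameter of the heterogeneous-coupling model
#'
#' At a synchronized steady state the balance \eqn{\omega_i = R K_i
#' \sin(\theta_i - \psi)} holds, so the steady phase depends on
#' \eqn{(\omega, K)} only through the combination \eqn{\omega/(R K)}:
#' \eqn{\theta_\infty = \psi + \arcsin(\omega / (R K))}.
#'
#' @param omega,k per-oscillator frequency and coupling.
#' @param r steady-state coherence.
#' @param psi mean phase (0 in the rotating frame).
#' @return steady-state phase(s).
#' @export
analytic_effective_parameter <- function(omega, k, r, psi = 0) {
  arg <- omega / (r * k)
  if (any(abs(arg) > 1))
    stop_invalid(paste("|omega/(R K)| > 1: oscillator drifts and has no",
                       "synchronized steady state"))
  psi + asin(arg)
}

#' Steady-state balance residuals of the firing model
#'
#' At a synchronized fixed point of the firing model,
#' \eqn{0 = \omega_i + \alpha_i \sin\theta_i + R K_i \sin(\psi - \theta_i)},
#' which rearranges to the balance
#' \deqn{(R K_i \cos\psi/\alpha_i - 1)\sin\theta_i -
#'   (R K_i/\alpha_i)\sin\psi \cos\theta_i = \omega_i/\alpha_i,}
#' reducing to \eqn{(R K_i/\alpha_i - 1)\sin\theta_i = \omega_i/\alpha_i}
#' when the mean phase is zero. The residual of that balance, evaluated per
#' oscillator, equals minus the phase velocity divided by \eqn{\alpha_i}
#' and so bounds the combined simulation and synchronization error --
#' amplified for the smallest firing coefficients.
#'
#' Unlike the rotation-invariant variants, the firing term pins the phase
#' axis: phases must be supplied in the frame in which the fixed point was
#' actually reached, together with that state's mean phase `psi`.
#'
#' @param theta steady phases (the model's own frame).
#' @param omega,alpha,k per-oscillator heterogeneities (alpha must be
#'   nonzero; an oscillator with alpha = 0 reduces to the plain balance of
#'   [analytic_effective_parameter()]).
#' @param r steady-state coherence.
#' @param psi mean phase of the steady state (default 0).
#' @return residual per oscillator.
#' @export
firing_balance_residual <- function(theta, omega, alpha, k, r, psi = 0) {
  if (any(alpha == 0))
    stop_invalid("alpha = 0: use the plain heterogeneous-coupling balance")
  (r * k * cos(psi) / alpha - 1) * sin(theta) -
    (r * k / alpha) * sin(psi) * cos(theta) - omega / alpha
}

#' Extract level sets of a scalar field on a regular grid
#'
#' Marching-squares contour extraction (via [grDevices::contourLines()]) of
#' a field sampled on a regular 2-D grid -- typically a discovered
#' effective parameter transferred from scattered oscillator
#' heterogeneities onto the grid by geometric harmonics. Each level set
#' collects the parameter combinations mapped to the same effective
#' parameter value, hence to the same steady-state phase.
#'
#' @param x,y increasing axis values of the grid.
#' @param z numeric matrix of field values, dim `c(length(x), length(y))`.
#' @param levels numeric vector of contour levels. Levels outside the range
#'   of `z` yield no contour (not an error).
#' @return an object of class `level_set_family`: a list of contours, each
#'   with `level`, `x`, `y`.
#' @export
extract_level_sets <- function(x, y, z, levels) {
  if (!is.matrix(z) || nrow(z) != length(x) || ncol(z) != length(y))
    stop_invalid("z must be a length(x) x length(y) matrix")
  contours <- contourLines(x = x, y = y, z = z, levels = levels)
  # contourLines fuzzes the field slightly to break degeneracies, so its
  # vertices can miss the exact linear crossing by ~1e-3; every vertex lies
  # on a grid edge, so re-solve the crossing on that edge exactly
  contours <- lapply(contours, refine_contour, x = x, y = y, z = z)
  structure(list(contours = contours, levels = levels,
                 x_range = range(x), y_range = range(y)),
            class = "level_set_family")
}

refine_contour <- function(ct, x, y, z) {
  tol <- 1e-8 * max(diff(range(x)), diff(range(y)))
  for (v in seq_along(ct$x)) {
    i <- findInterval(ct$x[v], x, all.inside = TRUE)
    j <- findInterval(ct$y[v], y, all.inside = TRUE)
    on_x <- abs(ct$x[v] - x[i]) < tol || abs(ct$x[v] - x[i + 1]) < tol
    on_y <- abs(ct$y[v] - y[j]) < tol || abs(ct$y[v] - y[j + 1]) < tol
    if (on_y && !on_x) { # crossing along an x-directed edge
      jj <- if (abs(ct$y[v] - y[j]) < tol) j else j + 1
      z0 <- z[i, jj]; z1 <- z[i + 1, jj]
      if (abs(z1 - z0) > .Machine$double.eps) {
        tt <- (ct$level - z0) / (z1 - z0)
        if (tt >= 0 && tt <= 1) ct$x[v] <- x[i] + tt * (x[i + 1] - x[i])
      }
    } else if (on_x && !on_y) { # crossing along a y-directed edge
      ii <- if (abs(ct$x[v] - x[i]) < tol) i else i + 1
      z0 <- z[ii, j]; z1 <- z[ii, j + 1]
      if (abs(z1 - z0) > .Machine$double.eps) {
        tt <- (ct$level - z0) / (z1 - z0)
        if (tt >= 0 && tt <= 1) ct$y[v] <- y[j] + tt * (y[j + 1] - y[j])
      }
    }
  }
  ct
}

#' @export
print.level_set_family <- function(x, ...) {
  cat(sprintf("<level_set_family: %d contour(s) at %d level(s)>\n",
              length(x$contours), length(x$levels)))
  invisible(x)
}

#' Transfer scattered eigenfunction values onto a regular parameter grid
#'
#' Fits geometric harmonics on the scattered (heterogeneity, phi) pairs and
#' evaluates them on a regular grid, the form [extract_level_sets()]
#' expects.
#'
#' @param points numeric matrix of scattered parameter locations (n x 2).
#' @param values eigenfunction values at `points`.
#' @param x,y grid axes.
#' @param n_harmonics retained geometric harmonics (default 10).
#' @param eps kernel bandwidth (default median heuristic).
#' @return matrix of dim `c(length(x), length(y))`.
#' @export
phi_on_grid <- function(points, values, x, y, n_harmonics = 10, eps = NULL) {
  model <- gh_fit(points, values, eps = eps, n_harmonics = n_harmonics)
  grid <- as.matrix(expand.grid(x = x, y = y))
  matrix(predict(model, grid), nrow = length(x))
}
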