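#' Build a phase-density snapshot dataset from trajectories
#'
#' Converts rotating-frame trajectories into a matrix of normalized phase
#' densities (one row per retained snapshot) together with the Kuramoto
#' coherence `R` of each snapshot. This is the featurization feeding the
#' coarse-variable discovery pipeline: the density is permutation-invariant
#' and captures the degree of phase clustering.
#'
#' @param trajectories a `kuramoto_trajectory` or list of them (rotating
#'   frame, transients already discarded).
#' @param n_bins number of histogram bins over [-pi, pi] (default 200).
#' @param stride keep every `stride`-th snapshot (default 1).
#' @return an object of class `density_dataset`: `densities` (snapshots x
#'   n_bins matrix of normalized densities), `R` labels, and `provenance`
#'   (trajectory id and time per row).
#' @export
build_density_dataset <- function(trajectories, n_bins = 200, stride = 1) {
  if (inherits(trajectories, "kuramoto_trajectory"))
    trajectories <- list(trajectories)
  rows <- list(); rlab <- list(); prov <- list()
  for (id in seq_along(trajectories)) {
    traj <- trajectories[[id]]
    stopifnot(inherits(traj, "kuramoto_trajectory"))
    keep <- seq(1, nrow(traj$phases), by = stride)
    dens <- t(vapply(keep, function(i) {
      phase_density(traj$phases[i, ], n_bins)$density
    }, numeric(n_bins)))
    op <- order_parameter(traj$phases[keep, , drop = FALSE])
    rows[[id]] <- dens
    rlab[[id]] <- op$R
    prov[[id]] <- data.frame(trajectory = id, time = traj$times[keep])
  }
  structure(
    list(densities = do.call(rbind, rows), R = unlist(rlab),
         provenance = do.call(rbind, prov), n_bins = n_bins),
    class = "density_dataset")
}

#' @export
print.density_dataset <- function(x, ...) {
  cat(sprintf("<density_dataset: %d snapshots x %d bins, R in [%.3f, %.3f]>\n",
              nrow(x$densities), x$n_bins, min(x$R), max(x$R)))
  invisible(x)
}

#' Discover a coarse variable from phase-density snapshots
#'
#' Runs the diffusion map on the density rows (Euclidean distance, Gaussian
#' kernel), computes local-linear-regression residuals, and flags the
#' significant eigenfunctions. Eigenfunction signs are fixed to correlate
#' positively with `R`, so the leading coordinate increases with coherence.
#'
#' @param dataset a [build_density_dataset()] result.
#' @param eps kernel bandwidth (default: median pairwise distance).
#' @param alpha density-normalization exponent (default 1, Laplace-Beltrami).
#' @param n_eig number of non-trivial eigenpairs (default 10).
#' @param threshold significance threshold on the LLR residuals.
#' @return a `dmap` object augmented with `residuals`, `significant`, and
#'   the snapshot labels `R`.
#' @export
discover_coarse_variable <- function(dataset, eps = NULL, alpha = 1,
                                     n_eig = 10, threshold = 0.5) {
  stopifnot(inherits(dataset, "density_dataset"))
  dm <- dmap(dataset$densities, eps = eps, alpha = alpha, n_eig = n_eig,
             sign_ref = dataset$R)
  dm$residuals <- llr_residuals(dm)
  dm$significant <- significant_of(dm, threshold)
  dm$R <- dataset$R
  dm
}

#' One-to-one correspondence diagnostics between a coordinate and R
#'
#' Quantifies whether a discovered coordinate `phi` is an invertible
#' function of the reference coarse variable `r`: the Spearman rank
#' correlation, the fraction of monotonicity violations of `phi` ordered by
#' `r`, and the range of local slopes of a smoothing-spline fit
#' (a monotone one-to-one relation has |rho| = 1, no violations, and slopes
#' bounded away from zero).
#'
#' @param phi numeric vector (discovered coordinate values).
#' @param r numeric vector (reference variable, e.g. coherence R).
#' @return list with `spearman`, `violation_fraction`, `slope_range`.
#' @export
check_one_to_one <- function(phi, r) {
  if (length(phi) != length(r)) stop_invalid("phi and r must match in length")
  if (length(unique(phi)) < 2 || length(unique(r)) < 2)
    stop_invalid("correlation undefined for constant input")
  rho <- cor(phi, r, method = "spearman")
  ord <- order(r)
  dphi <- diff(phi[ord])
  s <- sign(rho)
  violations <- mean(s * dphi < 0)
  fit <- stats::smooth.spline(r, phi, cv = FALSE)
  grid <- seq(min(r), max(r), length.out = 200)
  slopes <- stats::predict(fit, grid, deriv = 1)$y
  list(spearman = rho, violation_fraction = violations,
       slope_range = range(slopes))
}
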