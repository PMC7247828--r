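#' Generate flow-pair training data for the coherence dynamics
#'
#' Implements the initialization-integration procedure: each pair uses a
#' fresh all-to-all ensemble (new frequencies, new phases) initialized
#' either at R = 1 (identical phases) or R ~ 0 (uniformly random phases),
#' pre-integrated for a time chosen by inverting the closed-form
#' Ott-Antonsen flow so that the attained coherence values R(t) cover
#' [0, 1] approximately uniformly, then integrated exactly `dt` further to
#' yield the matched observation (R(t), R(t + dt)).
#'
#' Target coverage is a stratified-uniform sample of [0, 1]; each target is
#' served by the branch (growth from incoherence or decay from full
#' synchrony) on whose side of the Ott-Antonsen fixed point it falls.
#' Pre-integration times are capped at `t_cap`, which parks targets in the
#' unreachable neighborhood of the fixed point at (numerically) the fixed
#' point itself.
#'
#' @param n_pairs number of flow pairs (default 2000).
#' @param dt reporting horizon between the two observations.
#' @param n_oscillators ensemble size (default 8000).
#' @param k coupling constant (default 2).
#' @param gamma Cauchy frequency scale (default 0.5); frequencies are drawn
#'   i.i.d. from the tail-capped Cauchy law of
#'   [sample_cauchy_frequencies()].
#' @param seed integer seed; the full pair set is reproducible from it.
#' @param keep_phases if TRUE, retain the rotating-frame phase snapshots at
#'   both ends of every pair (needed to relearn dynamics in a discovered
#'   coordinate).
#' @param freq_eps quantile tail cap for the i.i.d. frequency draws
#'   (default 1e-5). The cap must sit well below the reporting horizon
#'   timescale: the heavy Cauchy tail is what produces the -gamma*R decay
#'   of the coherence near full synchrony, and capping at 1/(pi*eps*gamma)
#'   flattens that decay on times shorter than ~eps/gamma. The default
#'   keeps the flattened window two orders of magnitude below dt = 0.01
#'   while still bounding the stiffest oscillator.
#' @param t_cap cap on the pre-integration time (default 15).
#' @param atol,rtol integrator tolerances.
#' @return an object of class `flow_pairs`: vectors `start` and `end` of
#'   coherence values, `dt`, `branch` ("up"/"down"), `variable = "R"`, and
#'   optionally `phases_start` / `phases_end` matrices.
#' @export
generate_flow_pairs <- function(n_pairs = 2000, dt = 0.01,
                                n_oscillators = 8000, k = 2, gamma = 0.5,
                                seed = NULL, keep_phases = FALSE,
                                freq_eps = 1e-5, t_cap = 15, atol = 1e-7,
                                rtol = 1e-4) {
  if (dt <= 0) stop_invalid("dt must be > 0")
  if (n_pairs < 1) stop_invalid("n_pairs must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- n_oscillators
  rinf <- ott_antonsen_fixed_point(k, gamma)
  if (rinf <= 0)
    stop_invalid("k <= 2*gamma: only the incoherent state is attracting, so
 targets cannot cover [0, 1]")
  # stratified-uniform coverage targets for R(t)
  targets <- (seq_len(n_pairs) - runif(n_pairs)) / n_pairs
  targets <- sample(targets) # decouple target from pair index
  start <- end <- t_pre <- numeric(n_pairs)
  branch <- ifelse(targets >= rinf, "down", "up")
  if (keep_phases) {
    phases_start <- matrix(NA_real_, n_pairs, n)
    phases_end <- matrix(NA_real_, n_pairs, n)
  }
  for (i in seq_len(n_pairs)) {
    omega <- sample_cauchy_frequencies(n, gamma, eps = freq_eps,
                                       random = TRUE)
    ens <- oscillator_ensemble(omega, k = k)
    # Pre-integration times come from inverting the closed-form continuum
    # flow. The decay branch starts exactly at R = 1 and tracks the
    # continuum flow closely, so a single blind flight time suffices --
    # crucially, no decision ever conditions on a measured coherence, which
    # would select fluctuations and bias the subsequent reversion into the
    # observation window. The growth branch escapes incoherence noisily
    # (finite-N), so its flight is corrected mid-course from the measured
    # coherence; the corrections aim at a pre-target one time unit short of
    # the target, and the last time unit is always flown blind so the
    # conditioning decays away before the observation.
    if (branch[i] == "down") {
      theta <- rep(pi, n)
      t_used <- min(ott_antonsen_time(1, targets[i], k, gamma), t_cap)
      if (t_used > 0) {
        traj <- simulate_ensemble(ens, theta, c(0, t_used), atol = atol,
                                  rtol = rtol)
        theta <- traj$phases[2, ]
      }
    } else {
      theta <- runif(n, 0, 2 * pi)
      tau_blind <- min(1, t_cap / 2)
      pre_target <- ott_antonsen_flow(targets[i], -tau_blind, k, gamma)
      t_used <- 0
      for (stage in 1:3) {
        r_now <- order_parameter(theta)$R
        if (r_now >= pre_target) break
        t_rem <- ott_antonsen_time(r_now, pre_target, k, gamma)
        if (!is.finite(t_rem)) t_rem <- t_cap
        t_step <- min(if (stage == 1) 0.85 * t_rem else t_rem,
                      t_cap - tau_blind - t_used)
        if (t_step <= 0) break
        traj <- simulate_ensemble(ens, theta, c(0, t_step), atol = atol,
                                  rtol = rtol)
        theta <- traj$phases[2, ]
        t_used <- t_used + t_step
      }
      traj <- simulate_ensemble(ens, theta, c(0, tau_blind), atol = atol,
                                rtol = rtol)
      theta <- traj$phases[2, ]
      t_used <- t_used + tau_blind
    }
    t_pre[i] <- t_used
    step <- simulate_ensemble(ens, theta, c(0, dt), atol = atol,
                              rtol = rtol)
    th_s <- step$phases[1, ]
    th_e <- step$phases[2, ]
    op_s <- order_parameter(th_s)
    op_e <- order_parameter(th_e)
    start[i] <- op_s$R
    end[i] <- op_e$R
    if (keep_phases) {
      phases_start[i, ] <- th_s - op_s$psi
      phases_end[i, ] <- th_e - op_e$psi
    }
  }
  out <- list(start = start, end = end, dt = dt, branch = branch,
              targets = targets, t_pre = t_pre, variable = "R",
              n_oscillators = n, k = k, gamma = gamma, seed = seed)
  if (keep_phases) {
    out$phases_start <- phases_start
    out$phases_end <- phases_end
  }
  structure(out, class = "flow_pairs")
}

#' Construct a flow-pair set from raw vectors
#'
#' Lightweight constructor used when pairs come from a source other than
#' [generate_flow_pairs()] (synthetic ground-truth flows in tests, or a
#' discovered coordinate).
#'
#' @param start,end matched observations y(t), y(t + dt).
#' @param dt the (constant) reporting horizon.
#' @param variable tag, e.g. "R" or "phi1".
#' @return a `flow_pairs` object.
#' @export
flow_pairs <- function(start, end, dt, variable = "R") {
  if (length(start) != length(end))
    stop_invalid("start and end must have equal length")
  if (dt <= 0) stop_invalid("dt must be > 0")
  structure(list(start = as.numeric(start), end = as.numeric(end), dt = dt,
                 variable = variable),
            class = "flow_pairs")
}

#' @export
print.flow_pairs <- function(x, ...) {
  cat(sprintf("<flow_pairs: %d pairs of %s, dt = %g>\n",
              length(x$start), x$variable, x$dt))
  invisible(x)
}
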