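#' Learn the dynamics of a discovered coarse variable
#'
#' Re-runs the coarse-variable discovery on the phase snapshots retained
#' with a flow-pair set and learns the evolution law in the discovered
#' coordinate: all start and end snapshots are binned into phase densities
#' and embedded in ONE joint diffusion map, the single significant
#' eigenfunction phi_1 is extracted (signed to correlate positively with
#' R), matched pairs (phi_1(t), phi_1(t + dt)) are formed, and the
#' RK4-templated network is trained on them.
#'
#' Because the map from R to phi_1 is one-to-one but non-linear, a
#' uniformly sampled R domain becomes a non-uniformly sampled phi_1 domain;
#' the learned fit is accordingly expected to be somewhat less accurate
#' than the fit in R itself.
#'
#' @param pairs a [generate_flow_pairs()] result created with
#'   `keep_phases = TRUE`.
#' @param n_bins histogram bins for the density featurization (default 200).
#' @param eps diffusion map bandwidth (default: median heuristic).
#' @param alpha diffusion map normalization exponent (default 1).
#' @param threshold LLR significance threshold (default 0.5).
#' @param config an [rk4net_config()]; the default uses 50000 epochs, the
#'   harder training budget the biased phi_1 sampling requires.
#' @return list with `model` (the trained `rhs_model` in phi_1), `dmap`
#'   (the joint embedding with residuals), `pairs_phi` (the phi_1 flow
#'   pairs), and `correspondence` (the [check_one_to_one()] report of phi_1
#'   against R).
#' @export
learn_phi_dynamics <- function(pairs, n_bins = 200, eps = NULL, alpha = 1,
                               threshold = 0.5,
                               config = rk4net_config(epochs = 50000)) {
  stopifnot(inherits(pairs, "flow_pairs"))
  if (is.null(pairs$phases_start) || is.null(pairs$phases_end))
    stop_invalid("pairs must retain phase snapshots (keep_phases = TRUE)")
  n <- length(pairs$start)
  snaps <- rbind(pairs$phases_start, pairs$phases_end)
  dens <- t(apply(snaps, 1, function(th) phase_density(th, n_bins)$density))
  r_all <- c(pairs$start, pairs$end)
  dm <- dmap(dens, eps = eps, alpha = alpha, sign_ref = r_all)
  dm$residuals <- llr_residuals(dm)
  dm$significant <- significant_of(dm, threshold)
  dm$R <- r_all
  if (length(dm$significant) > 1)
    stop_invalid(paste("pipeline assumption violated: %d significant",
                       "eigenfunctions found, expected a single coarse",
                       "coordinate"), length(dm$significant))
  phi <- dm$eigenfunctions[, 1]
  pairs_phi <- flow_pairs(phi[seq_len(n)], phi[n + seq_len(n)], pairs$dt,
                          variable = "phi1")
  model <- train_rhs_net(pairs_phi, config)
  list(model = model, dmap = dm, pairs_phi = pairs_phi,
       correspondence = check_one_to_one(phi, r_all))
}
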