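#' Named parameter presets for the reference experiments
#'
#' Each preset bundles the study conditions of one reference computation:
#' `ref_coarse_id` (coarse-variable discovery from two all-to-all trajectories),
#' `ref_learn_rhs` (flow-pair generation and right-hand-side learning),
#' `ref_heterok` / `ref_firing` / `ref_chunglu` (effective-parameter discovery
#' for the heterogeneous-coupling, firing, and Chung-Lu variants).
#'
#' @return named list of preset parameter lists.
#' @export
experiment_presets <- function() {
  list(
    ref_coarse_id = list(experiment = "coarse-id", n = 8000, k = 2, gamma = 0.5,
                     freq_eps = 2.5e-4, n_bins = 200, eps = 1.54,
                     n_snapshots = 400, t_end = 25, t_transient = 0.5),
    ref_learn_rhs = list(experiment = "learn-rhs", n = 8000, k = 2, gamma = 0.5,
                   n_pairs = 2000, dts = c(0.01, 0.05), epochs = 10000,
                   epochs_phi = 50000, n_bins = 200),
    ref_heterok = list(experiment = "effective-params", variant = "heterok",
                     n = 1500, eps = 0.5),
    ref_firing = list(experiment = "effective-params", variant = "firing",
                     n = 1500, eps = 0.9),
    ref_chunglu = list(experiment = "effective-params", variant = "chung_lu",
                     n = 4000, eps = 2.3e-2)
  )
}

# Reduced problem sizes for quick runs. Histogram bins scale with N so the
# per-bin occupancy matches the full configuration, and fewer eigenpairs
# are examined because a smaller sample resolves fewer harmonics above its
# noise floor.
test_scale_overrides <- function(params) {
  small <- list(n = ceiling(params$n / 4))
  if (!is.null(params$n_pairs)) small$n_pairs <- ceiling(params$n_pairs / 4)
  if (!is.null(params$n_bins)) small$n_bins <- ceiling(params$n_bins / 4)
  small$n_eig <- if (identical(params$experiment, "effective-params")) 8
                 else 6
  params <- modifyList(params, small)
  if (identical(params$experiment, "coarse-id"))
    params$eps <- NULL # median heuristic adapts to the reduced sample
  params
}

#' Assemble an experiment configuration
#'
#' @param experiment one of "coarse-id", "learn-rhs", "learn-phi",
#'   "effective-params"; inferred from `preset` when given.
#' @param preset optional preset name, see [experiment_presets()].
#' @param scale "full" for the complete study conditions, "test" for reduced
#'   sizes.
#' @param seed integer seed for every random draw of the run.
#' @param out_dir output directory for artifacts (created if missing).
#' @param ... parameter overrides applied on top of the preset.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = NULL, preset = NULL,
                              scale = c("full", "test"), seed = 1,
                              out_dir = tempfile("oscgrain-run-"), ...) {
  scale <- match.arg(scale)
  params <- list()
  if (!is.null(preset)) {
    presets <- experiment_presets()
    if (!preset %in% names(presets))
      stop_invalid("unknown preset '%s'", preset)
    params <- presets[[preset]]
  }
  if (!is.null(experiment)) params$experiment <- experiment
  if (is.null(params$experiment))
    stop_invalid("an experiment tag or preset is required")
  known <- c("coarse-id", "learn-rhs", "learn-phi", "effective-params")
  if (!params$experiment %in% known)
    stop_invalid("unknown experiment '%s' (expected one of %s)",
                 params$experiment, paste(known, collapse = ", "))
  dots <- list(...)
  if (length(dots)) params <- modifyList(params, dots)
  if (scale == "test") params <- test_scale_overrides(params)
  structure(list(params = params, scale = scale, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

write_manifest <- function(config, path) {
  jsonlite::write_json(
    list(params = config$params, scale = config$scale, seed = config$seed,
         package_version = as.character(utils::packageVersion("oscgrain")),
         r_version = R.version.string),
    path, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run a configured experiment and write its artifact bundle
#'
#' Executes the pipeline named by the configuration, writes CSV/JSON
#' artifacts plus a `manifest.json` (configuration, seed, versions) and a
#' `summary.json` with the run's headline quantities (significant
#' eigenfunction count, correlations, maximum right-hand-side error against
#' the analytic oracle where one exists).
#'
#' @param config an [experiment_config()].
#' @return the summary list, invisibly.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(config, file.path(config$out_dir, "manifest.json"))
  set.seed(config$seed)
  summary <- switch(config$params$experiment,
                    "coarse-id" = run_coarse_id(config),
                    "learn-rhs" = run_learn_rhs(config),
                    "learn-phi" = run_learn_phi(config),
                    "effective-params" = run_effective_params(config))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

# Two relaxation trajectories bracketing the coherence fixed point, rotating
# frame, each sampled equidistantly over its own relaxation window. The
# window ends where the branch reaches the fixed-point neighborhood:
# sampling beyond it only accumulates snapshots whose coherence differs by
# finite-size noise, which carries no manifold structure. The branch
# started at full synchrony relaxes immediately, so its window starts after
# a short transient; the branch started at equally spaced phases dwells
# near incoherence until deterministic dephasing ejects it, so its window
# starts at the escape located by a coarse pre-scan.
reference_trajectories <- function(n, k, gamma, freq_eps, t_end, t_transient,
                                   n_snapshots) {
  omega <- sample_cauchy_frequencies(n, gamma, freq_eps)
  ens <- oscillator_ensemble(omega, k = k)
  theta_above <- rep(pi, n)
  theta_below <- seq(0, 2 * pi, length.out = n + 1)[-1]
  rinf <- ott_antonsen_fixed_point(k, gamma)
  window <- function(theta0, start_rule) {
    scan <- simulate_ensemble(ens, theta0, seq(0, t_end, 0.25))
    r <- order_parameter(scan$phases)$R
    t0 <- switch(start_rule,
                 transient = t_transient,
                 escape = max(scan$times[match(TRUE, r >= 0.05,
                                               nomatch = 2)] - 0.25,
                              t_transient))
    arrived <- abs(r - rinf) < 0.02 & scan$times > t0
    t1 <- if (any(arrived)) scan$times[match(TRUE, arrived)] else t_end
    c(t0, max(t1, t0 + 1))
  }
  make <- function(theta0, win) {
    times <- seq(win[1], win[2], length.out = n_snapshots)
    tr <- simulate_ensemble(ens, theta0, c(0, times))
    tr$phases <- tr$phases[-1, , drop = FALSE]
    tr$times <- tr$times[-1]
    to_rotating_frame(tr)
  }
  list(above = make(theta_above, window(theta_above, "transient")),
       below = make(theta_below, window(theta_below, "escape")))
}

run_coarse_id <- function(config) {
  p <- config$params
  trajs <- reference_trajectories(p$n, p$k, p$gamma,
                                  p$freq_eps %||% 2.5e-4, p$t_end %||% 25,
                                  p$t_transient %||% 0.5,
                                  p$n_snapshots %||% 400)
  dataset <- build_density_dataset(trajs, n_bins = p$n_bins %||% 200)
  dm <- discover_coarse_variable(dataset, eps = p$eps,
                                 n_eig = p$n_eig %||% 10)
  oto <- check_one_to_one(dm$eigenfunctions[, 1], dm$R)
  utils::write.csv(
    data.frame(R = dm$R, phi1 = dm$eigenfunctions[, 1]),
    file.path(config$out_dir, "coarse_variable.csv"), row.names = FALSE)
  list(experiment = "coarse-id",
       significant_count = length(dm$significant),
       residuals = dm$residuals, eigenvalues = dm$eigenvalues,
       spearman = oto$spearman, eps = dm$eps,
       n_snapshots = nrow(dataset$densities))
}

run_learn_rhs <- function(config) {
  p <- config$params
  grid <- seq(0, 1, length.out = 201)
  oracle <- ott_antonsen_rhs(grid, p$k, p$gamma)
  per_dt <- list()
  for (dt in p$dts) {
    pairs <- generate_flow_pairs(p$n_pairs, dt, p$n, p$k, p$gamma,
                                 seed = config$seed + round(1000 * dt))
    model <- train_rhs_net(pairs, rk4net_config(epochs = p$epochs,
                                                seed = config$seed))
    tag <- sprintf("dt_%g", dt)
    write_flow_pairs_csv(pairs,
                         file.path(config$out_dir,
                                   sprintf("pairs_%s.csv", tag)))
    write_rhs_model_json(model,
                         file.path(config$out_dir,
                                   sprintf("model_%s.json", tag)))
    per_dt[[tag]] <- list(
      dt = dt,
      max_rhs_error = max(abs(predict(model, grid) - oracle)),
      final_train_loss = model$history$train[p$epochs],
      final_val_loss = model$history$validation[p$epochs])
  }
  list(experiment = "learn-rhs", n_pairs = p$n_pairs, n = p$n,
       per_dt = per_dt,
       max_rhs_error = max(vapply(per_dt, `[[`, 0, "max_rhs_error")))
}

run_learn_phi <- function(config) {
  p <- config$params
  dt <- p$dts[1]
  pairs <- generate_flow_pairs(p$n_pairs, dt, p$n, p$k, p$gamma,
                               seed = config$seed, keep_phases = TRUE)
  res <- learn_phi_dynamics(pairs, n_bins = p$n_bins %||% 200,
                            config = rk4net_config(
                              epochs = p$epochs_phi %||% 50000,
                              seed = config$seed))
  write_rhs_model_json(res$model,
                       file.path(config$out_dir, "model_phi.json"))
  utils::write.csv(
    data.frame(phi1_t = res$pairs_phi$start, phi1_t_dt = res$pairs_phi$end),
    file.path(config$out_dir, "pairs_phi.csv"), row.names = FALSE)
  list(experiment = "learn-phi",
       significant_count = length(res$dmap$significant),
       spearman = res$correspondence$spearman,
       final_train_loss = res$model$history$train[nrow(res$model$history)])
}

run_effective_params <- function(config) {
  p <- config$params
  ds <- steady_state_dataset(p$variant, n = p$n, seed = config$seed)
  dm <- output_only_effective_param(ds, eps = p$eps,
                                    n_eig = p$n_eig %||% 10)
  oto <- check_one_to_one(dm$eigenfunctions[, 1], ds$theta)
  summary <- list(experiment = "effective-params", variant = p$variant,
                  n = length(ds$theta), R = ds$R,
                  significant_count = length(dm$significant),
                  residuals = dm$residuals,
                  spearman_phi_theta = oto$spearman)
  if (p$variant == "heterok") {
    summary$max_balance_residual <-
      max(abs(sin(ds$theta) -
                (ds$het$omega - ds$rotation) / (ds$R * ds$het$k)))
  } else if (p$variant == "firing") {
    summary$max_balance_residual <-
      max(abs(firing_balance_residual(wrap_phase(ds$theta + ds$psi),
                                      ds$het$omega, ds$het$alpha,
                                      ds$het$k, ds$R, psi = ds$psi)))
  }
  utils::write.csv(dm$het, file.path(config$out_dir, "effective_param.csv"),
                   row.names = FALSE)
  # level sets of phi1 in the first two heterogeneity coordinates
  pts <- as.matrix(dm$het[, 1:2])
  gx <- seq(min(pts[, 1]), max(pts[, 1]), length.out = 60)
  gy <- seq(min(pts[, 2]), max(pts[, 2]), length.out = 60)
  z <- phi_on_grid(pts, dm$het$phi1, gx, gy)
  lv <- quantile(dm$het$phi1, c(0.2, 0.4, 0.6, 0.8))
  ls <- extract_level_sets(gx, gy, z, lv)
  n_seg <- length(ls$contours)
  summary$n_level_set_segments <- n_seg
  summary
}
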