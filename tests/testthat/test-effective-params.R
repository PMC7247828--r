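# Scaled-down steady-state datasets shared across the blocks below. The
# firing fixture needs a few hundred oscillators: at very small N the
# near-zero-mean firing terms no longer average out and the ensemble
# settles into a small collective oscillation instead of a steady state.
ds_hk <- steady_state_dataset("heterok", n = 300, seed = 11)
ds_fi <- steady_state_dataset("firing", n = 800, seed = 12, t_max = 300)

test_that("steady-state datasets synchronize and embed on the unit circle", {
  for (ds in list(ds_hk, ds_fi)) {
    expect_true(ds$sync$vmax < 1e-4)
    expect_equal(sqrt(rowSums(ds$embedding^2)),
                 rep(1, length(ds$theta)))
    # rotating frame: mean phase is zero
    expect_lt(abs(order_parameter(ds$theta)$psi), 1e-10)
  }
  expect_named(ds_fi$het, c("omega", "k", "alpha"))
})

test_that("one output-only eigenfunction describes the steady phases", {
  # at a few hundred points the highest-order harmonics sit at the sampling
  # noise floor, so only as many eigenpairs are examined as the sample
  # resolves; the full-size datasets use the default spectrum
  for (ds in list(ds_hk, ds_fi)) {
    dm <- output_only_effective_param(ds, n_eig = 8)
    expect_identical(dm$significant, 1L)
    oto <- check_one_to_one(dm$eigenfunctions[, 1], ds$theta)
    expect_gt(abs(oto$spearman), 0.99)
    expect_true("phi1" %in% names(dm$het))
  }
})

test_that("steady phases satisfy the analytic synchronization balance", {
  # heterogeneous coupling: sin(theta) = (omega - rotation)/(R K) in the
  # frame co-rotating with the locked cluster (the finite-sample cluster
  # rotates at the 1/K-weighted mean frequency)
  resid <- sin(ds_hk$theta) -
    (ds_hk$het$omega - ds_hk$rotation) / (ds_hk$R * ds_hk$het$k)
  expect_lt(max(abs(resid)), 1e-3)
  # firing variant: evaluated at the fixed point in its own frame
  residf <- firing_balance_residual(wrap_phase(ds_fi$theta + ds_fi$psi),
                                    ds_fi$het$omega, ds_fi$het$alpha,
                                    ds_fi$het$k, ds_fi$R, psi = ds_fi$psi)
  expect_lt(max(abs(residf)), 1e-2)
})

test_that("the analytic effective parameter has the arcsin form", {
  expect_equal(analytic_effective_parameter(0, 20, 0.9, psi = 0.3), 0.3)
  expect_equal(analytic_effective_parameter(18, 20, 0.9, psi = 0),
               pi / 2)
  expect_error(analytic_effective_parameter(30, 20, 0.9), "drifts")
  # matches the simulated steady state (frame-relative frequencies)
  pred <- analytic_effective_parameter(ds_hk$het$omega - ds_hk$rotation,
                                       ds_hk$het$k, ds_hk$R)
  expect_lt(max(abs(sin(pred) - sin(ds_hk$theta))), 1e-3)
})

test_that("firing balance residual vanishes at its constructed roots", {
  omega <- c(0.3, -0.5)
  alpha <- c(1.5, 2)
  expect_equal(firing_balance_residual(-asin(omega / alpha), omega, alpha,
                                       k = c(0, 0), r = 0.7),
               c(0, 0))
  # general mean phase reduces to the zero-psi form
  expect_equal(
    firing_balance_residual(0.3, 0.5, 1.2, 15, 0.9, psi = 0),
    (0.9 * 15 / 1.2 - 1) * sin(0.3) - 0.5 / 1.2)
  expect_equal(firing_balance_residual(0, 0, 1.2, 10, 0.8), 0)
  expect_error(firing_balance_residual(0.1, 1, 0, 10, 0.8), "alpha")
})

test_that("level sets interpolate their level on the grid", {
  gx <- seq(0, 1, length.out = 41)
  gy <- seq(0, 2, length.out = 31)
  # linear field: contours are vertical lines
  z <- outer(gx, rep(1, 31))
  ls <- extract_level_sets(gx, gy, z, levels = c(0.25, 0.5))
  expect_gt(length(ls$contours), 0)
  for (ct in ls$contours) expect_lt(diff(range(ct$x)), 1e-12)
  # curved field: every contour vertex reproduces its level under the
  # bilinear interpolant of the grid
  zc <- outer(gx, gy, function(a, b) a / (0.2 + 0.5 * b))
  lsc <- extract_level_sets(gx, gy, zc, levels = c(0.5, 1.5))
  bilinear <- function(px, py) {
    i <- findInterval(px, gx, all.inside = TRUE)
    j <- findInterval(py, gy, all.inside = TRUE)
    tx <- (px - gx[i]) / diff(gx)[1]
    ty <- (py - gy[j]) / diff(gy)[1]
    (1 - tx) * (1 - ty) * zc[cbind(i, j)] + tx * (1 - ty) *
      zc[cbind(i + 1, j)] + (1 - tx) * ty * zc[cbind(i, j + 1)] +
      tx * ty * zc[cbind(i + 1, j + 1)]
  }
  for (ct in lsc$contours)
    expect_lt(max(abs(bilinear(ct$x, ct$y) - ct$level)), 1e-6)
  # levels beyond the field range give no contours, silently
  empty <- extract_level_sets(gx, gy, zc, levels = 99)
  expect_identical(length(empty$contours), 0L)
})

test_that("eigenfunction level sets are iso-phase sets in parameter space", {
  dm <- output_only_effective_param(ds_hk, n_eig = 8)
  pts <- as.matrix(dm$het[, c("omega", "k")])
  gx <- seq(quantile(pts[, 1], 0.05), quantile(pts[, 1], 0.95),
            length.out = 40)
  gy <- seq(quantile(pts[, 2], 0.05), quantile(pts[, 2], 0.95),
            length.out = 40)
  z <- phi_on_grid(pts, dm$het$phi1, gx, gy, n_harmonics = 20)
  # a level set of phi1 is an iso-phase set: the analytic steady phase
  # asin((omega - rotation)/(R K)) varies little along each contour (the
  # slack covers the geometric-harmonics transfer onto the grid)
  lv <- unname(quantile(dm$het$phi1, c(0.3, 0.6)))
  ls <- extract_level_sets(gx, gy, z, lv)
  expect_gt(length(ls$contours), 0)
  for (ct in ls$contours) {
    arg <- (ct$x - ds_hk$rotation) / (ds_hk$R * ct$y)
    th <- asin(pmin(1, pmax(-1, arg)))
    expect_lt(diff(range(th)), 0.1)
  }
})

test_that("steady phases depend weakly on the network realization", {
  # same heterogeneities, different Chung-Lu draws: the (omega, kappa) ->
  # theta relation overlaps across realizations
  n <- 400
  set.seed(13)
  omega <- runif(n, 0, 1)
  thetas <- list()
  kappas <- list()
  for (s in 1:3) {
    net <- chung_lu_network(n, 0.5, 0.9, 0.5, seed = 100 + s)
    ens <- oscillator_ensemble(omega, k = 20, adjacency = net$adjacency)
    ss <- simulate_to_steady(ens, runif(n, 0, 2 * pi), vtol = 1e-4)
    op <- order_parameter(ss$theta)
    thetas[[s]] <- wrap_phase(ss$theta - op$psi)
    kappas[[s]] <- net$degrees
  }
  # nearest neighbor in (omega, kappa) across realizations has a nearby
  # steady phase
  ref <- cbind(omega, kappas[[1]] / n)
  spread <- c()
  for (s in 2:3) {
    qry <- cbind(omega, kappas[[s]] / n)
    nn <- apply(qry, 1, function(p) {
      which.min((ref[, 1] - p[1])^2 + (ref[, 2] - p[2])^2)
    })
    spread <- c(spread, abs(thetas[[s]] - thetas[[1]][nn]))
  }
  expect_lt(stats::quantile(spread, 0.95), 0.05)
})
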