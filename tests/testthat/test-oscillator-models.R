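test_that("Cauchy inverse-transform sampling hits the closed-form quantiles", {
  # gamma * tan(pi * (u - 1/2)) at u = 0.25, 0.5, 0.75
  expect_equal(sample_cauchy_frequencies(3, gamma = 0.5, eps = 0.25),
               c(-0.5, 0, 0.5))
  # symmetric quantiles give a zero median for any odd n
  for (n in c(5, 11, 101))
    expect_equal(median(sample_cauchy_frequencies(n, gamma = 1.7)), 0)
  # the tail cap bounds the largest frequency
  om <- sample_cauchy_frequencies(8000, gamma = 0.5, eps = 2.5e-4)
  expect_equal(max(abs(om)), 0.5 * tan(pi * (0.5 - 2.5e-4)))
  expect_error(sample_cauchy_frequencies(5, gamma = -1), "gamma")
  expect_error(sample_cauchy_frequencies(5, eps = 0.5), "eps")
})

test_that("Chung-Lu weights, probabilities and degrees follow the model", {
  net <- chung_lu_network(4000, p = 0.5, q = 0.9, r = 0.5, seed = 1)
  expect_equal(net$weights[1], 4000 * 0.5) # w_1 = N p
  expect_equal(net$weights[4000],
               4000 * 0.5 * (1 - 0.9 * 3999 / 4000)^0.5)
  expect_true(all(net$prob >= 0 & net$prob <= 1))
  expect_identical(net$adjacency, t(net$adjacency))
  expect_true(all(diag(net$adjacency) == 0))
  expect_true(all(net$adjacency %in% c(0, 1)))
  expect_equal(net$degrees, rowSums(net$adjacency))
  expect_error(chung_lu_network(100, p = 0.5, q = 2, r = 0.5),
               "non-integer")
})

test_that("realized Chung-Lu degrees concentrate on the expected degrees", {
  n <- 60
  probe <- c(1, 20, 40, 60)
  draws <- 300
  deg <- matrix(0, draws, length(probe))
  for (s in seq_len(draws)) {
    net <- chung_lu_network(n, p = 0.4, q = 0.8, r = 0.7, seed = s)
    deg[s, ] <- net$degrees[probe]
  }
  expected <- {
    net <- chung_lu_network(n, p = 0.4, q = 0.8, r = 0.7, seed = 1)
    rowSums(net$prob)[probe]
  }
  se <- sqrt(colSums(matrix(1, draws, 1)) * 0 + apply(deg, 2, var) / draws)
  expect_true(all(abs(colMeans(deg) - expected) < 3 * se + 1e-9))
})

test_that("mean-field right-hand-side matches the pairwise sum", {
  set.seed(4)
  for (variant in c("all2all", "heterok", "firing", "network")) {
    n <- 50
    omega <- rnorm(n)
    theta <- runif(n, -pi, pi)
    ens <- switch(variant,
      all2all = oscillator_ensemble(omega, k = 2),
      heterok = oscillator_ensemble(omega, k = runif(n, 1, 5)),
      firing = oscillator_ensemble(omega, k = runif(n, 1, 5),
                                   alpha = runif(n, -2, 2)),
      network = oscillator_ensemble(omega, k = 2,
        adjacency = chung_lu_network(n, 0.4, 0.8, 0.6, seed = 9)$adjacency))
    expect_lt(max(abs(kuramoto_rhs(ens, theta) -
                      kuramoto_rhs_pairwise(ens, theta))), 1e-12)
    # compiled kernel agrees with the R implementation
    a <- oscgrain:::ensemble_cpp_args(ens)
    expect_lt(max(abs(oscgrain:::.cpp_kuramoto_rhs(
      a$variant, theta, a$omega, a$kvec, a$alpha, a$kglobal, a$A) -
      kuramoto_rhs(ens, theta))), 1e-12)
  }
})

test_that("right-hand-side limiting cases", {
  n <- 20
  omega <- rnorm(n)
  ens <- oscillator_ensemble(omega, k = 3)
  # equal phases: coupling vanishes
  expect_equal(kuramoto_rhs(ens, rep(1.3, n)), omega)
  # firing fixed point at K = 0: theta = -asin(omega / alpha)
  alpha <- runif(n, 1.5, 2)
  omega2 <- runif(n, -1, 1)
  ensf <- oscillator_ensemble(omega2, k = rep(0, n), alpha = alpha)
  expect_lt(max(abs(kuramoto_rhs(ensf, -asin(omega2 / alpha)))), 1e-12)
  # adjacency plus per-oscillator coupling is rejected as ambiguous
  expect_error(oscillator_ensemble(omega, k = rep(1, n),
                                   adjacency = diag(0, n)), "ambiguous")
})

test_that("integration reproduces decoupled and two-oscillator dynamics", {
  # single uncoupled oscillator: linear phase growth
  ens1 <- oscillator_ensemble(0.7, k = 0)
  tr <- simulate_ensemble(ens1, 0.2, seq(0, 10, 1))
  expect_equal(tr$phases[, 1], 0.2 + 0.7 * seq(0, 10, 1), tolerance = 1e-6)
  # two identical oscillators attract to zero phase difference
  ens2 <- oscillator_ensemble(c(1, 1), k = 2)
  tr2 <- simulate_ensemble(ens2, c(0.2, 2.2), seq(0, 20, 5),
                           atol = 1e-12, rtol = 1e-10)
  gap <- abs(tr2$phases[, 1] - tr2$phases[, 2])
  expect_lt(tail(gap, 1), 1e-6)
  expect_true(all(diff(gap[1:3]) < 0))
})

test_that("order parameter matches hand-computed cases and stays in [0, 1]", {
  op <- order_parameter(rep(pi, 7))
  expect_equal(op$R, 1)
  expect_equal(op$psi, pi)
  expect_lt(order_parameter(spaced_phases(64))$R, 1e-12)
  op2 <- order_parameter(c(0, pi / 2))
  expect_equal(op2$R, sqrt(2) / 2)
  expect_equal(op2$psi, pi / 4)
  expect_error(order_parameter(numeric(0)), "empty")
  set.seed(1)
  tr <- simulate_ensemble(tiny_ensemble(100), runif(100, 0, 2 * pi),
                          seq(0, 5, 0.5))
  ops <- order_parameter_series(tr)
  expect_true(all(ops$R >= 0 & ops$R <= 1))
})

test_that("rotating frame zeroes the mean phase and preserves coherence", {
  set.seed(2)
  tr <- simulate_ensemble(tiny_ensemble(80), runif(80, 0, 2 * pi),
                          seq(0, 4, 0.25))
  rot <- to_rotating_frame(tr)
  ops <- order_parameter(rot$phases)
  expect_true(all(abs(ops$psi) < 1e-10))
  expect_equal(ops$R, order_parameter(tr$phases)$R)
  # rigid rotation maps to constant phases
  ci <- seq(-0.5, 0.5, length.out = 11)
  times <- seq(0, 3, 0.5)
  rigid <- structure(list(times = times,
                          phases = outer(2 * times, rep(1, 11)) +
                            matrix(ci, length(times), 11, byrow = TRUE),
                          frame = "stationary"),
                     class = "kuramoto_trajectory")
  rotr <- to_rotating_frame(rigid)
  # constant per oscillator, up to the 2*pi branch of the mean phase
  expect_lt(max(abs(wrap_phase(sweep(rotr$phases, 2, rotr$phases[1, ])))),
            1e-12)
})

test_that("phase density bins wrapped phases with the right mass", {
  pd <- phase_density(rep(0, 1000), n_bins = 200)
  expect_equal(sum(pd$counts), 1000)
  expect_equal(sum(pd$counts > 0), 1L)
  expect_equal(sum(pd$density) * 2 * pi / 200, 1)
  th <- runif(500, -pi, pi)
  expect_identical(phase_density(th)$counts, phase_density(th + 2 * pi)$counts)
  # uniform phases: per-bin counts within 5 binomial standard deviations
  set.seed(3)
  n <- 1e5
  pdu <- phase_density(runif(n, -pi, pi), n_bins = 200)
  sd_bin <- sqrt(n * (1 / 200) * (1 - 1 / 200))
  expect_true(all(abs(pdu$counts - n / 200) < 5 * sd_bin))
})

test_that("coherence, mean phase and density are permutation invariant", {
  set.seed(5)
  th <- runif(300, -4, 9)
  perm <- sample(300)
  expect_identical(order_parameter(th)$R, order_parameter(th[perm])$R)
  expect_identical(order_parameter(th)$psi, order_parameter(th[perm])$psi)
  expect_identical(phase_density(th)$counts, phase_density(th[perm])$counts)
})

test_that("synchronizing regimes reach a rotating-frame steady state", {
  set.seed(6)
  n <- 120
  ens <- oscillator_ensemble(runif(n, -pi, pi), k = runif(n, 10, 100))
  ss <- simulate_to_steady(ens, runif(n, 0, 2 * pi), vtol = 1e-4)
  expect_true(ss$synchronized)
  expect_lt(max(abs(rotating_frame_velocity(ens, ss$theta))), 1e-4)
  # a hopeless regime errors instead of looping forever
  ens0 <- oscillator_ensemble(c(-3, 3), k = 0.1)
  expect_error(simulate_to_steady(ens0, c(0, 1), t_max = 2),
               "incomplete synchronization")
})
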