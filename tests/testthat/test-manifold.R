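test_that("diffusion map operator is Markov with a constant leading pair", {
  set.seed(1)
  x <- matrix(rnorm(120 * 3), 120)
  dm <- dmap(x, n_eig = 5)
  expect_equal(dm$trivial$value, 1, tolerance = 1e-10)
  expect_lt(diff(range(dm$trivial$vector)), 1e-8)
  expect_true(all(abs(c(dm$trivial$value, dm$eigenvalues)) <= 1 + 1e-10))
  expect_true(all(diff(dm$eigenvalues) <= 1e-12))
})

test_that("a circle embeds in a cosine/sine eigenfunction pair", {
  ang <- seq(0, 2 * pi, length.out = 501)[-1]
  dm <- dmap(cbind(cos(ang), sin(ang)), alpha = 1)
  # Laplace-Beltrami on S^1: the leading pair is a degenerate cos/sin pair
  expect_lt(dm$eigenvalues[1] / dm$eigenvalues[2] - 1, 0.05)
  # the embedding traces a closed curve: radius in the (phi1, phi2) plane
  # is nearly constant and the winding is monotone in the angle
  rad <- sqrt(dm$eigenfunctions[, 1]^2 + dm$eigenfunctions[, 2]^2)
  expect_lt(diff(range(rad)) / mean(rad), 0.1)
})

test_that("duplicated points share their embedding coordinates", {
  set.seed(2)
  x <- matrix(runif(60 * 2), 60)
  dm <- dmap(rbind(x, x), n_eig = 4)
  expect_equal(dm$eigenfunctions[1:60, ], dm$eigenfunctions[61:120, ],
               tolerance = 1e-9)
})

test_that("rescaling data and bandwidth together leaves eigenfunctions fixed", {
  set.seed(3)
  x <- matrix(rnorm(100 * 2), 100)
  dm1 <- dmap(x, eps = 0.8, n_eig = 4, sign_ref = x[, 1])
  dm2 <- dmap(5 * x, eps = 4, n_eig = 4, sign_ref = x[, 1])
  expect_equal(dm1$eigenvalues, dm2$eigenvalues, tolerance = 1e-8)
  expect_equal(dm1$eigenfunctions, dm2$eigenfunctions, tolerance = 1e-8)
})

test_that("a numerically diagonal kernel is rejected", {
  x <- matrix(seq(0, 10, length.out = 30), ncol = 1)
  expect_error(dmap(x, eps = 1e-4, n_eig = 3), "diagonal")
})

test_that("LLR residuals separate fundamentals from harmonics", {
  dm <- dmap(arc_points(300), alpha = 1)
  res <- llr_residuals(dm)
  expect_equal(res[1], 1) # convention: no predecessors
  expect_lt(res[2], 0.2)  # phi2 is a harmonic of phi1 on a 1-D arc
  expect_identical(select_significant(res), 1L)
  # 2:1 rectangle: exactly two independent directions among the first 8
  set.seed(4)
  rect <- cbind(runif(600, 0, 2), runif(600, 0, 1))
  resr <- llr_residuals(dmap(rect, alpha = 1, n_eig = 8))
  expect_identical(length(select_significant(resr)), 2L)
})

test_that("significance selection applies the threshold in order", {
  expect_identical(select_significant(c(1.0, 0.05, 0.03)), 1L)
  expect_identical(select_significant(c(1.0, 0.2, 0.9, 0.1), 0.5),
                   c(1L, 3L))
  expect_identical(select_significant(c(0.8, 0.6, 0.4), threshold = 0.7), 1L)
})

test_that("geometric harmonics reproduce training values with full spectrum", {
  set.seed(5)
  x <- matrix(sort(runif(40)), ncol = 1)
  f <- sin(2 * x[, 1]) + x[, 1]^2
  # small bandwidth keeps the kernel well conditioned, so no truncation
  m <- gh_fit(x, f, eps = 0.02, n_harmonics = 40)
  expect_equal(length(m$lambda), 40L)
  expect_lt(max(abs(predict(m, x) - f)), 1e-8)
})

test_that("geometric harmonics extend constants and linear functions", {
  xtr <- matrix(seq(0, 1, length.out = 200), ncol = 1)
  mc <- gh_fit(xtr, rep(3.7, 200), n_harmonics = 10)
  inner <- matrix(seq(0.1, 0.9, length.out = 50), ncol = 1)
  expect_lt(max(abs(predict(mc, inner) - 3.7)), 1e-3)
  ml <- gh_fit(xtr, xtr[, 1], n_harmonics = 10)
  interleaved <- matrix(seq(0.0025, 0.9975, length.out = 199), ncol = 1)
  expect_lt(max(abs(predict(ml, interleaved) - interleaved[, 1])), 1e-2)
})

test_that("ill-conditioned harmonics are truncated with a warning", {
  x <- matrix(seq(0, 1, length.out = 50), ncol = 1)
  expect_warning(gh_fit(x, sin(x[, 1]), eps = 2, n_harmonics = 50),
                 "truncating")
})
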