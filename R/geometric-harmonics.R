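#' Fit a geometric harmonics extension model
#'
#' Geometric harmonics extend a function known at sampled points to new
#' points on (or near) the sampled manifold through the eigendecomposition
#' of a symmetric Gaussian kernel: with kernel matrix eigenpairs
#' \eqn{(\lambda_l, \psi^{(l)})}, the extension is \eqn{f = K_{new} \Psi
#' \Lambda^{-1} \Psi^T F}. With all n harmonics retained, extension at the
#' training points reproduces F exactly.
#'
#' @param x numeric matrix of training points (rows) or a vector.
#' @param f numeric vector of function values at the training points.
#' @param eps kernel bandwidth; default is the median pairwise distance of
#'   the training points.
#' @param n_harmonics number of retained eigenpairs d <= n (default 10).
#'   Eigenvalues below `cutoff * lambda_1` are truncated with a warning.
#' @param cutoff relative conditioning cutoff for retained eigenvalues.
#' @return an object of class `geometric_harmonics`.
#' @export
gh_fit <- function(x, f, eps = NULL, n_harmonics = 10, cutoff = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(f) != n) stop_invalid("f must have one value per training point")
  if (n_harmonics > n) stop_invalid("n_harmonics must be <= n = %d", n)
  if (is.null(eps)) eps <- median_pairwise_distance(x)
  if (!is.numeric(eps) || eps <= 0) stop_invalid("eps must be > 0")
  k <- exp(-as.matrix(dist(x))^2 / (2 * eps^2))
  ek <- eigen(k, symmetric = TRUE)
  keep <- seq_len(n_harmonics)
  lam <- ek$values[keep]
  ok <- lam > cutoff * abs(ek$values[1])
  if (!all(ok)) {
    warning(sprintf(
      "truncating %d geometric harmonics with eigenvalues below the %g cutoff",
      sum(!ok), cutoff), call. = FALSE)
    keep <- keep[ok]
    lam <- lam[ok]
  }
  psi <- ek$vectors[, keep, drop = FALSE]
  structure(
    list(x = x, eps = eps, lambda = lam, psi = psi,
         coef = psi %*% (crossprod(psi, f) / lam), f = f),
    class = "geometric_harmonics")
}

#' @export
print.geometric_harmonics <- function(x, ...) {
  cat(sprintf("<geometric_harmonics: %d training points, %d harmonics, eps = %.4g>\n",
              nrow(x$x), length(x$lambda), x$eps))
  invisible(x)
}

#' Evaluate a geometric harmonics extension at new points
#'
#' @param object a [gh_fit()] model.
#' @param newdata numeric matrix (or vector) of evaluation points.
#' @param ... unused.
#' @return numeric vector of extended function values.
#' @export
predict.geometric_harmonics <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop_invalid("newdata must have %d columns", ncol(object$x))
  # cross-kernel between new and training points
  d2 <- outer(rowSums(newdata^2), rowSums(object$x^2), "+") -
    2 * tcrossprod(newdata, object$x)
  d2[d2 < 0] <- 0
  kn <- exp(-d2 / (2 * object$eps^2))
  drop(kn %*% object$coef)
}
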