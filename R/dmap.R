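#' Diffusion map embedding with alpha-normalization
#'
#' Builds the Gaussian kernel \eqn{K_{ij} = \exp(-\|x_i - x_j\|^2 /
#' (2\epsilon^2))}, applies the density normalization \eqn{\tilde K =
#' D^{-\alpha} K D^{-\alpha}} and row-normalizes to the Markov operator
#' \eqn{A = \tilde D^{-1} \tilde K}. Eigenpairs are computed on the
#' symmetric conjugate \eqn{\tilde D^{-1/2} \tilde K \tilde D^{-1/2}} for
#' numerical stability and transformed back, so all eigenvalues are real
#' with \eqn{\lambda_0 = 1} and a constant leading eigenfunction.
#'
#' The trivial constant pair is reported but excluded from the numbering of
#' the embedding coordinates: `eigenfunctions[, k]` is \eqn{\phi_k}, the
#' k-th non-trivial coordinate. Each eigenfunction's sign is fixed so that
#' its correlation with `sign_ref` (default: the first data coordinate) is
#' non-negative, making embeddings reproducible.
#'
#' @param x numeric matrix, one observation per row (or a vector).
#' @param eps kernel bandwidth; default is the median of the pairwise
#'   distances.
#' @param alpha density-normalization exponent: 0 (graph Laplacian), 0.5
#'   (Fokker-Planck) or 1 (Laplace-Beltrami, removes sampling-density
#'   effects; the default).
#' @param n_eig number of non-trivial eigenpairs to return (default 10).
#' @param sign_ref numeric vector used to fix eigenfunction signs.
#' @return an object of class `dmap` with `eigenvalues` (length n_eig,
#'   descending, excluding the trivial 1), `eigenfunctions` (n x n_eig),
#'   `trivial` (list with the constant pair), `eps`, `alpha`.
#' @export
dmap <- function(x, eps = NULL, alpha = 1, n_eig = 10, sign_ref = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < n_eig + 1)
    stop_invalid("need at least n_eig + 1 = %d observations", n_eig + 1)
  d2 <- as.matrix(dist(x))^2
  if (is.null(eps)) eps <- sqrt(median(d2[upper.tri(d2)]))
  if (!is.numeric(eps) || eps <= 0) stop_invalid("eps must be > 0")
  k <- exp(-d2 / (2 * eps^2))
  offdiag_max <- max(k[upper.tri(k)])
  if (offdiag_max < 1e-300)
    stop_invalid("kernel matrix is numerically diagonal; increase eps")
  if (offdiag_max < 1e-12)
    warning("kernel bandwidth is very small relative to the data scale; ",
            "the operator is close to diagonal", call. = FALSE)
  if (alpha != 0) {
    dd <- rowSums(k)
    k <- k / (outer(dd, dd)^alpha)
  }
  dt <- rowSums(k)
  inv_sqrt <- 1 / sqrt(dt)
  s <- k * outer(inv_sqrt, inv_sqrt)
  es <- eigen(s, symmetric = TRUE)
  m <- n_eig + 1
  vals <- es$values[seq_len(m)]
  phi <- es$vectors[, seq_len(m), drop = FALSE] * inv_sqrt
  # normalize columns and fix signs
  phi <- sweep(phi, 2, sqrt(colSums(phi^2)), "/")
  if (is.null(sign_ref)) sign_ref <- x[, 1]
  for (j in seq_len(m)) {
    cr <- sum(phi[, j] * (sign_ref - mean(sign_ref)))
    if (cr < 0 || (cr == 0 && sum(phi[, j]) < 0)) phi[, j] <- -phi[, j]
  }
  structure(
    list(eigenvalues = vals[-1], eigenfunctions = phi[, -1, drop = FALSE],
         trivial = list(value = vals[1], vector = phi[, 1]),
         eps = eps, alpha = alpha, n = n),
    class = "dmap")
}

#' @export
print.dmap <- function(x, ...) {
  cat(sprintf("<dmap: %d points, eps = %.4g, alpha = %g>\n", x$n, x$eps,
              x$alpha))
  cat("eigenvalues:", format(signif(x$eigenvalues, 4)), "\n")
  if (!is.null(x$residuals)) {
    cat("LLR residuals:", format(signif(x$residuals, 3)), "\n")
    cat("significant: ", paste(x$significant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Local-linear-regression residuals of diffusion map eigenfunctions
#'
#' Detects "harmonic" (repeated) eigenfunctions: each \eqn{\phi_k} (k >= 2)
#' is fitted locally as an affine function of the preceding eigenfunctions
#' \eqn{\Phi_{k-1} = [\phi_1, ..., \phi_{k-1}]} with Gaussian kernel
#' weights \eqn{\exp(-\|\Phi_{k-1}(i) - \Phi_{k-1}(j)\|^2 /
#' \epsilon_{reg}^2)} and leave-one-out weighting (j != i). The normalized
#' residual
#' \deqn{r_k = \sqrt{\sum_i (\phi_k(i) - \hat\phi_k(i))^2 /
#'   \sum_i \phi_k(i)^2}}
#' is near zero for harmonics and near one for eigenfunctions carrying a
#' new direction. By convention \eqn{r_1 = 1} (no predecessors).
#'
#' @param phi matrix of non-trivial eigenfunctions in eigenvalue order
#'   (columns), or a `dmap` object.
#' @param eps_reg regression kernel scale; default one third of the median
#'   pairwise distance among the \eqn{\Phi_{k-1}} rows, recomputed per k.
#' @param ridge relative ridge jitter for degenerate local systems.
#' @return numeric vector of residuals, one per eigenfunction.
#' @export
llr_residuals <- function(phi, eps_reg = NULL, ridge = 1e-10) {
  if (inherits(phi, "dmap")) phi <- phi$eigenfunctions
  phi <- as.matrix(phi)
  n <- nrow(phi)
  m <- ncol(phi)
  res <- rep(NA_real_, m)
  res[1] <- 1
  if (m == 1) return(res)
  for (k in 2:m) {
    pred <- phi[, seq_len(k - 1), drop = FALSE]
    target <- phi[, k]
    er <- eps_reg %||% (median_pairwise_distance(pred) / 3)
    if (er <= 0) er <- .Machine$double.eps
    d2 <- as.matrix(dist(pred))^2
    w <- exp(-d2 / er^2)
    diag(w) <- 0 # leave-one-out
    xmat <- cbind(1, pred)
    p <- ncol(xmat)
    fitted <- numeric(n)
    for (i in seq_len(n)) {
      wi <- w[i, ]
      xw <- xmat * wi
      xtx <- crossprod(xw, xmat)
      xty <- crossprod(xw, target)
      reg <- ridge * max(sum(diag(xtx)), .Machine$double.eps)
      coef <- NULL
      # escalate the ridge until the local system solves cleanly; points
      # isolated in Phi-space otherwise produce wild extrapolations
      for (boost in c(1, 1e4, 1e8)) {
        xtx_r <- xtx + diag(reg * boost, p)
        coef <- tryCatch(solve(xtx_r, xty), error = function(e) NULL)
        if (!is.null(coef) && all(is.finite(coef))) break
      }
      if (is.null(coef) || !all(is.finite(coef)))
        coef <- c(sum(wi * target) / max(sum(wi), .Machine$double.eps),
                  rep(0, p - 1))
      fitted[i] <- sum(xmat[i, ] * coef)
    }
    # a leave-one-out fit can be arbitrarily worse than the zero predictor;
    # anything at or above 1 means "no predictive relation", so cap there
    res[k] <- min(1, sqrt(sum((target - fitted)^2) / sum(target^2)))
  }
  res
}

#' Indices of significant (non-harmonic) eigenfunctions
#'
#' @param residuals vector from [llr_residuals()].
#' @param threshold residuals above this value flag a significant
#'   eigenfunction (default 0.5).
#' @return integer indices in eigenvalue order.
#' @export
select_significant <- function(residuals, threshold = 0.5) {
  which(residuals > threshold)
}

# Significant eigenfunctions of an embedding: high LLR residual AND
# non-negligible spectral weight. Eigenfunctions whose eigenvalue is a tiny
# fraction of the leading one contribute nothing to diffusion distances;
# they are discretization/sampling noise, which no earlier coordinate can
# predict, so the residual alone would mistake them for new directions.
significant_of <- function(dm, threshold = 0.5, lambda_floor = 1e-3) {
  sig <- select_significant(dm$residuals, threshold)
  sig[dm$eigenvalues[sig] > lambda_floor * dm$eigenvalues[1]]
}
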