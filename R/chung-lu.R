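#' Generate a Chung-Lu random network
#'
#' Builds the expected-degree weight sequence
#' \eqn{w_i = N p (1 - q (i-1)/N)^r}, the connection probabilities
#' \eqn{P_{ij} = \min(w_i w_j / \sum_k w_k, 1)}, and one Bernoulli adjacency
#' realization (symmetric, zero diagonal).
#'
#' @param n number of nodes (>= 2).
#' @param p,q,r network parameters; all weights must come out positive.
#' @param seed optional integer seed for the adjacency draw.
#' @return an object of class `chung_lu_network` with fields `weights`,
#'   `prob` (N x N), `adjacency` (N x N 0/1), `degrees` (row sums of the
#'   adjacency), and `params`.
#' @examples
#' net <- chung_lu_network(50, p = 0.5, q = 0.9, r = 0.5, seed = 1)
#' net$weights[1] == 50 * 0.5
#' @export
chung_lu_network <- function(n, p, q, r, seed = NULL) {
  if (n < 2) stop_invalid("n must be >= 2")
  base <- 1 - q * (seq_len(n) - 1) / n
  if (any(base < 0) && r != round(r))
    stop_invalid("negative weight base with non-integer exponent r")
  w <- n * p * base^r
  if (any(!is.finite(w)) || any(w <= 0))
    stop_invalid("parameters must yield positive weights w_i")
  prob <- pmin(outer(w, w) / sum(w), 1)
  diag(prob) <- 0
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.numeric(runif(sum(ut)) < prob[ut])
  a <- a + t(a)
  structure(
    list(weights = w, prob = prob, adjacency = a, degrees = rowSums(a),
         params = list(p = p, q = q, r = r, seed = seed, n = n)),
    class = "chung_lu_network")
}

#' @export
print.chung_lu_network <- function(x, ...) {
  cat(sprintf(
    "<chung_lu_network: N = %d, p = %g, q = %g, r = %g, mean degree %.1f>\n",
    x$params$n, x$params$p, x$params$q, x$params$r, mean(x$degrees)))
  invisible(x)
}
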