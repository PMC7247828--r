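#' Sample natural frequencies from a (tail-capped) Cauchy distribution
#'
#' Frequencies are generated by inverse-transform sampling of the Cauchy
#' quantile function \eqn{\omega = \gamma \tan(\pi (u - 1/2))}. With
#' `random = FALSE` the quantiles are `n` equally spaced values spanning
#' `[eps, 1 - eps]`, which yields a systematic, symmetric sample that
#' suppresses finite-sample noise in the order parameter. With
#' `random = TRUE` the quantiles are drawn i.i.d. uniformly on
#' `(eps, 1 - eps)`, giving independent draws from the same tail-capped
#' Cauchy law. The cap `eps` bounds the largest attainable `|omega|` at
#' \eqn{\gamma \tan(\pi(1/2 - \epsilon))}, which keeps the stiffest
#' oscillators integrable.
#'
#' @param n number of oscillators.
#' @param gamma Cauchy scale parameter (> 0).
#' @param eps quantile tail cap, 0 < eps < 0.5. Default 2.5e-4.
#' @param random if TRUE draw quantiles i.i.d. instead of equally spaced.
#' @return numeric vector of `n` frequencies.
#' @examples
#' sample_cauchy_frequencies(3, gamma = 0.5, eps = 0.25) # -0.5, 0, 0.5
#' @export
sample_cauchy_frequencies <- function(n, gamma = 0.5, eps = 2.5e-4,
                                      random = FALSE) {
  if (!is.numeric(gamma) || gamma <= 0) stop_invalid("gamma must be > 0")
  if (!is.numeric(eps) || eps <= 0 || eps >= 0.5)
    stop_invalid("eps must lie in (0, 0.5)")
  if (n < 1) stop_invalid("n must be >= 1")
  u <- if (random) runif(n, eps, 1 - eps)
       else if (n == 1) 0.5
       else seq(eps, 1 - eps, length.out = n)
  gamma * tan(pi * (u - 0.5))
}
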