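#' Euler + geometric-harmonics baseline derivative estimator
#'
#' The finite-difference baseline the network approach is compared against:
#' raw forward-Euler estimates \eqn{(y(t+\Delta t) - y(t))/\Delta t} at the
#' pair start values, smoothed by a geometric-harmonics interpolation with
#' `n_gh` retained harmonics.
#'
#' @param pairs a [flow_pairs()] set with constant dt.
#' @param n_gh number of geometric harmonics (default 10).
#' @param eps kernel bandwidth passed to [gh_fit()] (default median
#'   heuristic).
#' @return an object of class `euler_gh_baseline`: the raw Euler estimates
#'   and a smoothed evaluator; use `predict()` to evaluate it.
#' @export
baseline_euler_gh <- function(pairs, n_gh = 10, eps = NULL) {
  stopifnot(inherits(pairs, "flow_pairs"))
  euler <- (pairs$end - pairs$start) / pairs$dt
  model <- gh_fit(matrix(pairs$start, ncol = 1), euler, eps = eps,
                  n_harmonics = n_gh)
  structure(list(euler = euler, at = pairs$start, model = model,
                 variable = pairs$variable),
            class = "euler_gh_baseline")
}

#' @export
print.euler_gh_baseline <- function(x, ...) {
  cat(sprintf("<euler_gh_baseline: %d Euler estimates of d%s/dt, %d harmonics>\n",
              length(x$euler), x$variable, length(x$model$lambda)))
  invisible(x)
}

#' @export
predict.euler_gh_baseline <- function(object, y, ...) {
  predict(object$model, matrix(as.numeric(y), ncol = 1))
}
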