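#' Configuration for the RK4-templated right-hand-side network
#'
#' @param hidden integer vector of hidden-layer widths (default three layers
#'   of 24 units).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs training epochs (full-batch; default 10000).
#' @param validation_fraction fraction of pairs held out to monitor
#'   overfitting (default 0.1). No early stopping is applied.
#' @param seed seed for the Glorot initialization and the train/validation
#'   shuffle.
#' @param activation hidden-layer activation, "tanh" (default) or "relu".
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param lr_final_fraction optional geometric learning-rate decay: the rate
#'   reaches `learning_rate * lr_final_fraction` at the last epoch. The
#'   default 1 keeps the rate constant, the reference training schedule.
#'   Constant-rate full-batch Adam stalls in a bounce floor proportional to
#'   the rate, so decay is useful when chasing a noiseless target.
#' @return a list of class `rk4net_config`.
#' @export
rk4net_config <- function(hidden = c(24, 24, 24), learning_rate = 1e-3,
                          epochs = 10000, validation_fraction = 0.1,
                          seed = 1, activation = c("tanh", "relu"),
                          beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                          lr_final_fraction = 1) {
  activation <- match.arg(activation)
  if (any(hidden < 1)) stop_invalid("hidden widths must be positive")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop_invalid("validation_fraction must be in [0, 1)")
  if (lr_final_fraction <= 0 || lr_final_fraction > 1)
    stop_invalid("lr_final_fraction must be in (0, 1]")
  structure(list(hidden = as.integer(hidden),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), activation = activation,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 lr_final_fraction = lr_final_fraction),
            class = "rk4net_config")
}

# Glorot-uniform kernels, zero biases, flattened in layer order
glorot_init <- function(widths, seed) {
  set.seed(seed)
  flat <- numeric(0)
  for (l in seq_len(length(widths) - 1)) {
    fi <- widths[l]; fo <- widths[l + 1]
    limit <- sqrt(6 / (fi + fo))
    flat <- c(flat, runif(fi * fo, -limit, limit), rep(0, fo))
  }
  flat
}

#' Train an RK4-templated network on flow pairs
#'
#' Learns an approximation of the ODE right-hand-side \eqn{f} governing the
#' observed variable: the network prediction is one fixed-step fourth-order
#' Runge-Kutta step of the sub-network \eqn{\hat f} applied to y(t), and
#' the mean squared error against y(t + dt) is minimized by full-batch
#' Adam. Kernels are initialized with the uniform Glorot scheme, biases at
#' zero.
#'
#' The sub-network standardizes its input by the training-set mean and
#' standard deviation (stored with the model and applied identically at all
#' four integration stages). This is an affine reparametrization of the
#' same function family, but it conditions the optimization: with raw
#' inputs confined to a small or one-sided range, the fit of the steepest
#' part of the right-hand-side converges erratically within a fixed epoch
#' budget.
#'
#' @param pairs a [flow_pairs()] / [generate_flow_pairs()] set.
#' @param config an [rk4net_config()].
#' @return an object of class `rhs_model`: the trained parameters, the
#'   architecture, the training/validation loss curves, and the training
#'   domain.
#' @export
train_rhs_net <- function(pairs, config = rk4net_config()) {
  stopifnot(inherits(pairs, "flow_pairs"))
  n <- length(pairs$start)
  if (n < 50) stop_invalid("need at least 50 flow pairs (got %d)", n)
  widths <- c(1L, config$hidden, 1L)
  flat0 <- glorot_init(widths, config$seed)
  idx <- sample(n) # seeded by glorot_init's set.seed
  n_val <- floor(config$validation_fraction * n)
  val <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  tr <- setdiff(idx, val)
  act <- if (config$activation == "tanh") 0L else 1L
  mu <- mean(pairs$start[tr])
  sigma <- stats::sd(pairs$start[tr])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  fit <- .cpp_rk4net_train(flat0, widths, pairs$start[tr], pairs$end[tr],
                           pairs$start[val], pairs$end[val], pairs$dt,
                           config$learning_rate, config$epochs, config$beta1,
                           config$beta2, config$adam_eps, act,
                           config$lr_final_fraction %||% 1, mu, sigma)
  structure(
    list(params = fit$params, widths = widths, activation = act,
         mu = mu, sigma = sigma,
         dt = pairs$dt, variable = pairs$variable, config = config,
         domain = range(pairs$start),
         history = data.frame(epoch = seq_len(config$epochs),
                              train = fit$train_loss,
                              validation = if (n_val > 0) fit$val_loss
                                           else NA_real_)),
    class = "rhs_model")
}

#' @export
print.rhs_model <- function(x, ...) {
  cat(sprintf(
    "<rhs_model for %s: layers %s, dt = %g, final train loss %.3g>\n",
    x$variable, paste(x$widths, collapse = "-"), x$dt,
    x$history$train[nrow(x$history)]))
  invisible(x)
}

#' Evaluate a learned right-hand-side
#'
#' @param object a trained `rhs_model`.
#' @param y state value(s).
#' @param ... unused.
#' @return the learned time derivative \eqn{\hat f(y)}.
#' @export
predict.rhs_model <- function(object, y, ...) {
  .cpp_mlp_forward(object$params, object$widths, as.numeric(y),
                   object$activation, object$mu %||% 0, object$sigma %||% 1)
}

#' Roll out a learned model with fixed-step RK4
#'
#' @param model a trained `rhs_model`.
#' @param y0 initial state.
#' @param times increasing reporting grid.
#' @param h internal step size (default: the model's training dt).
#' @return numeric vector of states at `times`.
#' @export
integrate_learned <- function(model, y0, times, h = NULL) {
  stopifnot(inherits(model, "rhs_model"))
  f <- function(y) predict(model, y)
  out <- integrate_rk4(f, y0, times, h = h %||% model$dt)
  if (identical(model$variable, "R") &&
      (min(out) < -0.1 || max(out) > 1.1))
    warning("trajectory escaped the coherence domain [-0.1, 1.1]",
            call. = FALSE)
  out
}
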