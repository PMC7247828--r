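#' Wrap angles into the half-open interval [-pi, pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles reduced modulo 2*pi into [-pi, pi).
#' @export
wrap_phase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Median of pairwise Euclidean distances
#'
#' The standard starting heuristic for kernel bandwidth selection.
#'
#' @param x numeric matrix (rows are observations) or vector.
#' @return median pairwise distance (a scalar).
#' @export
median_pairwise_distance <- function(x) {
  x <- as.matrix(x)
  median(dist(x))
}
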