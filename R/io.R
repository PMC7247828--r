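#' Write / read a trajectory as CSV
#'
#' Columns: `time`, then one column per oscillator (`theta_1`, ...).
#'
#' @param trajectory a `kuramoto_trajectory`.
#' @param path output file.
#' @return `path`, invisibly (writer); a `kuramoto_trajectory` (reader).
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "kuramoto_trajectory"))
  df <- data.frame(time = trajectory$times, trajectory$phases)
  names(df) <- c("time", paste0("theta_", seq_len(ncol(trajectory$phases))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param frame frame tag to attach on read.
#' @export
read_trajectory_csv <- function(path, frame = "stationary") {
  df <- read.csv(path)
  structure(list(times = df$time,
                 phases = as.matrix(df[, -1, drop = FALSE]),
                 frame = frame),
            class = "kuramoto_trajectory")
}

#' Write / read a flow-pair set as CSV
#'
#' Columns: `t_value`, `t_plus_dt_value`, `dt`, `branch`, `seed`. Retained
#' phase snapshots are not persisted.
#'
#' @param pairs a `flow_pairs` object.
#' @param path output file.
#' @return `path`, invisibly (writer); a `flow_pairs` (reader).
#' @export
write_flow_pairs_csv <- function(pairs, path) {
  stopifnot(inherits(pairs, "flow_pairs"))
  df <- data.frame(t_value = pairs$start, t_plus_dt_value = pairs$end,
                   dt = pairs$dt,
                   branch = pairs$branch %||% NA_character_,
                   seed = pairs$seed %||% NA_integer_)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_pairs_csv
#' @param variable variable tag to attach on read.
#' @export
read_flow_pairs_csv <- function(path, variable = "R") {
  df <- read.csv(path)
  out <- flow_pairs(df$t_value, df$t_plus_dt_value, df$dt[1], variable)
  out$branch <- df$branch
  out$seed <- df$seed[1]
  out
}

#' Persist a Chung-Lu network as an edge list plus a JSON parameter record
#'
#' @param network a [chung_lu_network()].
#' @param edge_path CSV path for the edge list (columns `i`, `j`, i < j).
#' @param json_path JSON path for the parameters and a weight summary.
#' @return `edge_path`, invisibly.
#' @export
write_network_csv <- function(network, edge_path, json_path = NULL) {
  stopifnot(inherits(network, "chung_lu_network"))
  idx <- which(upper.tri(network$adjacency) & network$adjacency == 1,
               arr.ind = TRUE)
  write.csv(data.frame(i = idx[, 1], j = idx[, 2]), edge_path,
            row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(params = network$params,
           weights = list(min = min(network$weights),
                          max = max(network$weights),
                          mean = mean(network$weights))),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(edge_path)
}

#' Persist / restore a trained right-hand-side model as JSON
#'
#' The parameter dump (layer widths plus flattened weights) keeps the
#' format language-portable.
#'
#' @param model a trained `rhs_model`.
#' @param path JSON file path.
#' @return `path`, invisibly (writer); an `rhs_model` (reader).
#' @export
write_rhs_model_json <- function(model, path) {
  stopifnot(inherits(model, "rhs_model"))
  jsonlite::write_json(
    list(widths = model$widths, params = model$params,
         activation = model$activation, dt = model$dt,
         variable = model$variable, domain = model$domain,
         mu = model$mu %||% 0, sigma = model$sigma %||% 1),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rhs_model_json
#' @export
read_rhs_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(params = as.numeric(x$params),
                 widths = as.integer(x$widths),
                 activation = as.integer(x$activation), dt = x$dt,
                 variable = x$variable, domain = as.numeric(x$domain),
                 mu = x$mu %||% 0, sigma = x$sigma %||% 1,
                 history = NULL, config = NULL),
            class = "rhs_model")
}
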