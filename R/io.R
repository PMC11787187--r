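#' Write a trajectory to tidy CSV with a JSON metadata sidecar
#'
#' Size-resolved trajectories are written long (`time,size,concentration`,
#' with the monomer as size 1); moment trajectories wide
#' (`time,P,M,m[,lambda]`); network trajectories long with a `node` column.
#' The sidecar (`<path>.meta.json`) records the model, parameters,
#' truncation and solver tolerances needed to reproduce the run.
#'
#' @param traj an `aggregation_trajectory`, `moment_trajectory` or
#'   `network_trajectory`.
#' @param path CSV output path.
#' @param meta_path sidecar path; default `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             meta_path = paste0(path, ".meta.json")) {
  df <- if (inherits(traj, "aggregation_trajectory")) {
    sizes <- as.integer(colnames(traj$p))
    data.frame(
      time = rep(traj$time, times = 1L + length(sizes)),
      size = rep(c(1L, sizes), each = length(traj$time)),
      concentration = c(traj$m, as.vector(traj$p)))
  } else if (inherits(traj, "moment_trajectory")) {
    out <- data.frame(time = traj$time, P = traj$P, M = traj$M, m = traj$m)
    if (!is.null(traj$lambda)) out$lambda <- traj$lambda
    out
  } else if (inherits(traj, "network_trajectory") && is.null(traj$p)) {
    nodes <- colnames(traj$M)
    data.frame(time = rep(traj$time, times = length(nodes)),
               node = rep(nodes, each = length(traj$time)),
               P = as.vector(traj$P), M = as.vector(traj$M))
  } else if (inherits(traj, "network_trajectory")) {
    sizes <- as.integer(dimnames(traj$p)[[2L]])
    nodes <- dimnames(traj$p)[[3L]]
    data.frame(
      time = rep(traj$time, times = length(sizes) * length(nodes)),
      node = rep(nodes, each = length(traj$time) * length(sizes)),
      size = rep(rep(sizes, each = length(traj$time)),
                 times = length(nodes)),
      concentration = as.vector(traj$p))
  } else stop("unsupported trajectory class", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- traj$meta
  meta$params <- unclass(meta$params)
  meta <- meta[!vapply(meta, is.function, logical(1L))]
  meta <- lapply(meta, function(x) if (inherits(x, c("clearance_spec",
                                                     "damage_spec",
                                                     "dosing_regime")))
    unclass(x) else x)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a config block to a clearance_spec; accepts an existing spec,
# a named list, or a compact string like "constant:10"
as_clearance_spec <- function(x) {
  if (inherits(x, "clearance_spec")) return(x)
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
    variant <- parts[1L]
    vals <- as.numeric(parts[-1L])
    return(switch(variant,
      constant = clearance_spec("constant", lambda = vals[1L]),
      linear_in_size = clearance_spec("linear_in_size", lambda0 = vals[1L]),
      inverse_size = clearance_spec("inverse_size", lambda0 = vals[1L]),
      windowed = clearance_spec("windowed", lambda_a = vals[1L],
                                lambda_drug = vals[2L], n0 = vals[3L],
                                n1 = vals[4L]),
      stop("cannot parse clearance string '", x, "'", call. = FALSE)))
  }
  if (is.list(x)) return(do.call(clearance_spec, x))
  stop("invalid clearance configuration", call. = FALSE)
}
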