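config_error <- function(...) {
  stop(structure(class = c("amynet_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Run a configured simulation end to end
#'
#' Binds a configuration (a list, a [make_fixture()] result, or a path to a
#' YAML/JSON file) to the appropriate simulator, writes the trajectory CSV,
#' a machine-readable `summary.json` and a `run.log` into `out_dir`, and
#' returns the summary. Configuration fields:
#'
#' * `model`: one of `"invitro"`, `"invivo"`, `"damage"`, `"network"`,
#'   `"therapy"`.
#' * `parameters`: named list of kinetic parameters (or a parameter file
#'   path); defaults to the reference Abeta42 set in micromolar-hour units.
#' * `clearance` / `damage` / `dosing`: the model-specific block.
#' * `seed_dimer`: dimer seed as a fraction of `m_0` (default `1e-4`).
#' * `t_end`, `N`, `moments`, `include_kn`, `rng_seed`: as in the
#'   simulators.
#'
#' @param config configuration list or file path.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   artifact writing.
#' @return The summary list, invisibly when artifacts are written.
#' @export
run_simulation <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or file path")
  model <- config$model
  if (is.null(model) ||
      !model %in% c("invitro", "invivo", "damage", "network", "therapy"))
    config_error("config field `model` must be one of invitro, invivo, ",
                 "damage, network, therapy; got '",
                 if (is.null(model)) "NULL" else model, "'")
  params <- if (is.null(config$parameters)) abeta_parameters()
  else if (is.character(config$parameters)) read_parameters(config$parameters)
  else tryCatch(do.call(kinetic_parameters, config$parameters),
                error = function(e) config_error("bad `parameters` block: ",
                                                 conditionMessage(e)))
  rng_seed <- config$rng_seed %||% 1L
  set.seed(rng_seed)
  t_end <- config$t_end %||% 1
  seed_frac <- config$seed_dimer %||% 1e-4
  include_kn <- isTRUE(config$include_kn)
  summary <- list(model = model, rng_seed = rng_seed,
                  conc_scale = params$conc_scale)
  traj <- NULL

  if (model == "invitro") {
    N <- config$N %||% 200
    traj <- simulate_invitro(params, t_end = t_end, N = N)
    summary$halftime_numeric <- halftime_numeric(traj)
    summary$halftime_linear <- halftime_linear(params)
    summary$final_mass <- traj$M[length(traj$M)]
  } else if (model == "invivo") {
    if (is.null(config$clearance)) config_error("`clearance` block required")
    spec <- tryCatch(as_clearance_spec(config$clearance),
                     error = function(e)
                       config_error("bad `clearance` block: ",
                                    conditionMessage(e)))
    if (spec$variant %in% c("constant", "linear_in_size", "inverse_size"))
      summary$lambda_crit <- critical_clearance(params, spec$variant)
    if (spec$variant == "constant") {
      fp <- fixed_point_constant(params, spec$lambda)
      summary$M2 <- fp$M_star
      summary$P2 <- fp$P_star
    }
    if (!is.null(config$window_starts)) {
      w <- config$window_width %||% 10
      masses <- vapply(config$window_starts, function(n0)
        interval_mass_reduction(params, spec$lambda_a, spec$lambda_drug,
                                n0, n0 + w), numeric(1L))
      summary$window_starts <- config$window_starts
      summary$window_equilibrium_mass <- masses
    }
    if (isTRUE(config$moments) && spec$variant == "constant") {
      traj <- simulate_invivo_moments(params, spec$lambda,
                                      P0 = seed_frac * params$m_0,
                                      t_end = t_end,
                                      include_kn = include_kn)
      pk <- peak_and_timescales(traj, epsilon = 0.01 * max(traj$M))
      summary$M_max <- pk$M_max
      summary$tau1 <- pk$tau1
      summary$tau2 <- pk$tau2
    } else if (is.null(config$window_starts)) {
      N <- config$N %||% 300
      traj <- simulate_invivo(params, spec,
                              seed = seed_frac * params$m_0,
                              t_end = t_end, N = N,
                              include_kn = include_kn)
      summary$final_mass <- traj$M[length(traj$M)]
    }
  } else if (model == "damage") {
    if (is.null(config$damage)) config_error("`damage` block required")
    d <- config$damage
    dspec <- tryCatch(damage_spec(d$beta, d$mu, d$lambda_init),
                      error = function(e)
                        config_error("bad `damage` block: ",
                                     conditionMessage(e)))
    summary$regime <- as.character(classify_regime(dspec, params))
    summary$mu_crit <- attr(classify_regime(dspec, params), "mu_crit")
    traj <- if (isTRUE(config$moments))
      simulate_damage_moments(params, dspec, P0 = seed_frac * params$m_0,
                              M0 = 2 * seed_frac * params$m_0,
                              t_end = t_end, include_kn = include_kn)
    else simulate_damage(params, dspec, seed = seed_frac * params$m_0,
                         t_end = t_end, N = config$N %||% 300,
                         include_kn = include_kn)
    summary$final_lambda <- utils::tail(
      if (is.matrix(traj$lambda)) traj$lambda[, 1L] else traj$lambda, 1L)
  } else if (model == "network") {
    cn <- if (!is.null(config$connectome)) {
      if (grepl("\\.graphml$", config$connectome))
        read_graphml(config$connectome)
      else read_edgelist(config$connectome)
    } else {
      g <- config$graph %||% list()
      generate_connectome(V = g$V %||% 20,
                          mean_degree = g$mean_degree %||% 6,
                          rewire_p = g$rewire_p %||% 0.1,
                          rng_seed = g$rng_seed %||% rng_seed)
    }
    spec <- as_clearance_spec(config$clearance %||%
                                list(variant = "constant", lambda = 10))
    if (isTRUE(config$moments)) {
      if (spec$variant != "constant")
        config_error("moment-level network runs need constant clearance")
      traj <- simulate_network_moments(cn, params, spec$lambda,
                                       rho = config$rho %||% 0.01,
                                       seed_node = config$seed_node %||%
                                         cn$labels[1L],
                                       seed_type = config$seed_type %||%
                                         "mass",
                                       t_end = t_end,
                                       include_kn = include_kn)
    } else {
      N <- config$N %||% 40
      rho <- diffusion_profile(config$rho %||% 0.01,
                               config$diffusion_mode %||% "constant", N)
      traj <- simulate_network(cn, params, spec, rho,
                               seed_node = config$seed_node %||%
                                 cn$labels[1L],
                               seed_type = config$seed_type %||% "mass",
                               t_end = t_end, N = N,
                               include_kn = include_kn)
    }
    inv <- invasion_metrics(traj)
    summary$invasion <- inv
    summary$lambda_crit <- if (spec$variant == "constant")
      critical_clearance(params, "constant") else NULL
  } else if (model == "therapy") {
    if (is.null(config$dosing)) config_error("`dosing` block required")
    d <- config$dosing
    if (!is.null(d$C_max)) {
      opts <- lapply(d$C_max, function(cm)
        optimize_regime(params, C_max = cm,
                        lambda_a = d$lambda_a %||% 10, A = d$A %||% 1,
                        t_max = d$t_max %||% 28,
                        n_B = d$n_B %||% 8))
      summary$C_max <- d$C_max
      summary$optimal_B <- vapply(opts, `[[`, numeric(1L), "B")
      summary$optimal_lambda_drug <- vapply(opts, `[[`, numeric(1L),
                                            "lambda_drug")
      summary$optimal_M_bar <- vapply(opts, `[[`, numeric(1L), "M_bar")
    } else {
      reg <- dosing_regime(d$lambda_drug, A = d$A %||% 1, B = d$B %||% 1,
                           lambda_a = d$lambda_a %||% 10,
                           t_max = d$t_max %||% 28)
      sim <- simulate_dosing(params, reg)
      traj <- sim$cycle
      summary$C_max <- reg$C_max
      summary$M_bar <- cycle_average_mass(sim)
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(traj))
      write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "columns")
    writeLines(c(paste("amynet version:",
                       as.character(utils::packageVersion("amynet"))),
                 paste("model:", model),
                 paste("rng_seed:", rng_seed),
                 paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 paste("solver: lsoda, rtol 1e-8, atol 1e-12 * m_0")),
               file.path(out_dir, "run.log"))
    return(invisible(summary))
  }
  summary
}
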