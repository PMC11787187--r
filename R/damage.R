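#' Clearance-damage (aging) specification
#'
#' Toxic mass degrades the brain's clearance mechanisms: each per-size
#' clearance rate relaxes from its initial value toward a basal capacity at
#' a rate proportional to the toxic mass,
#' `d lambda_i/dt = beta_i M (mu_i - lambda_i)`. Clearance only decays
#' (`mu_i <= lambda_init_i`); there is no recovery mechanism.
#'
#' @param beta damage rate coefficient, 1/(concentration * time); scalar or
#'   per-size vector.
#' @param mu basal clearance capacity (the floor), 1/time; scalar or
#'   per-size vector.
#' @param lambda_init initial clearance, 1/time; scalar or per-size vector,
#'   elementwise `>= mu`.
#' @return An object of class `damage_spec`.
#' @export
damage_spec <- function(beta, mu, lambda_init) {
  if (any(beta < 0)) stop("`beta` must be non-negative", call. = FALSE)
  if (any(mu < 0) || any(lambda_init < 0))
    stop("clearance rates must be non-negative", call. = FALSE)
  n <- max(length(beta), length(mu), length(lambda_init))
  if (any(rep_len(mu, n) > rep_len(lambda_init, n)))
    stop("`mu` must not exceed `lambda_init` (clearance decays downward)",
         call. = FALSE)
  structure(list(beta = beta, mu = mu, lambda_init = lambda_init),
            class = "damage_spec")
}

#' @export
print.damage_spec <- function(x, ...) {
  cat("Damage spec: beta =", format(x$beta), ", mu =", format(x$mu),
      ", lambda_init =", format(x$lambda_init), "\n")
  invisible(x)
}

#' Simulate the in vivo model with dynamic clearance damage
#'
#' Couples the size-resolved in vivo master equations to the clearance
#' degradation law `d lambda_i/dt = beta_i M (mu_i - lambda_i)`. Clearance
#' decays monotonically from `lambda_init` toward `mu`; once it has
#' relaxed, the dynamics coincide with [simulate_invivo()] at constant
#' clearance `mu`. Homogeneous primary nucleation (`k_n m_0^2`) is included
#' by default here: the slow nucleation source is what drives the long
#' clearance decay in unseeded tissue.
#'
#' @inheritParams simulate_invivo
#' @param dspec a [damage_spec()]; scalar fields are recycled across sizes.
#' @return An `aggregation_trajectory` with an additional `lambda` matrix
#'   (one column per size) giving the clearance series.
#' @export
simulate_damage <- function(params, dspec, seed = NULL, t_end = 1, N = 300,
                            include_kn = TRUE, times = NULL, n_out = 201,
                            rtol = 1e-8, atol = 1e-12 * params$m_0) {
  stopifnot(inherits(dspec, "damage_spec"))
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  n_sz <- N - 1L
  beta <- rep_len(dspec$beta, n_sz)
  mu <- rep_len(dspec$mu, n_sz)
  lam0 <- rep_len(dspec$lambda_init, n_sz)
  p0 <- rep(0, n_sz)
  if (!is.null(seed)) p0[seq_along(seed)] <- seed
  m0 <- params$m_0
  sizes <- seq(2L, N)
  kn_src <- if (include_kn) params$k_n * m0^2 else 0
  f_el <- 2 * params$k_plus * m0
  deriv <- function(t, y, parms) {
    p <- y[seq_len(n_sz)]
    lam <- y[n_sz + seq_len(n_sz)]
    M <- sum(sizes * p)
    sig <- params$K_M / (params$K_M + M^2)
    nuc2 <- params$k_2 * sig * m0^2 * M
    f <- f_el * p
    f[n_sz] <- 0
    dp <- -lam * p + c(kn_src + nuc2, rep(0, n_sz - 1L)) +
      c(0, f[-n_sz]) - f
    dlam <- beta * M * (mu - lam)
    list(c(dp, dlam))
  }
  sol <- deSolve::ode(y = c(p0, lam0), times = times, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  lam_mat <- sol[, 1L + n_sz + seq_len(n_sz), drop = FALSE]
  colnames(lam_mat) <- sizes
  sol_p <- cbind(sol[, 1L], m0, sol[, 1L + seq_len(n_sz), drop = FALSE])
  build_trajectory(sol_p, params, N, rtol, atol, model = "damage",
                   extra = list(lambda = lam_mat, damage = dspec))
}

#' Simulate the damage model at moment level (uniform clearance)
#'
#' For size-uniform `beta`, `mu` and `lambda_init` the damage system closes
#' over `(P, M, lambda)`; useful when the basal clearance capacity is small
#' enough that the equilibrium size distribution would require a very large
#' size-resolved truncation.
#'
#' @inheritParams simulate_invivo_moments
#' @param dspec a [damage_spec()] with scalar fields.
#' @return A `moment_trajectory` with an additional `lambda` series.
#' @export
simulate_damage_moments <- function(params, dspec, P0 = 0, M0 = 0,
                                    t_end = 1, include_kn = TRUE,
                                    times = NULL, n_out = 401,
                                    rtol = 1e-8,
                                    atol = 1e-12 * params$m_0) {
  stopifnot(inherits(dspec, "damage_spec"))
  if (length(dspec$beta) != 1L || length(dspec$mu) != 1L ||
      length(dspec$lambda_init) != 1L)
    stop("moment-level damage simulation requires size-uniform beta, mu ",
         "and lambda_init", call. = FALSE)
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  m0 <- params$m_0
  kn_src <- if (include_kn) params$k_n * m0^2 else 0
  deriv <- function(t, y, parms) {
    P <- y[1L]; M <- y[2L]; lam <- y[3L]
    sig <- params$K_M / (params$K_M + M^2)
    nuc2 <- params$k_2 * sig * m0^2 * M
    list(c(-lam * P + kn_src + nuc2,
           -lam * M + 2 * kn_src + 2 * params$k_plus * m0 * P + 2 * nuc2,
           dspec$beta * M * (dspec$mu - lam)))
  }
  sol <- deSolve::ode(y = c(P = P0, M = M0, lambda = dspec$lambda_init),
                      times = times, func = deriv, parms = NULL,
                      method = "vode", rtol = rtol, atol = atol)
  structure(list(time = sol[, 1L], P = sol[, 2L], M = sol[, 3L],
                 m = rep(m0, nrow(sol)), lambda = sol[, 4L],
                 meta = list(model = "damage_moments", params = params,
                             damage = dspec, include_kn = include_kn,
                             rtol = rtol, atol = atol, method = "vode")),
            class = "moment_trajectory")
}

#' Classify the damage-model parameter regime
#'
#' Relative to the critical basal clearance capacity
#' `mu_crit = critical_clearance(params, "constant")`, a size-uniform
#' damage specification falls in one of three regimes:
#'
#' * `"subcritical_start"` (`lambda_init < mu_crit`): aggregation can invade
#'   from the outset; when seeded, the zero-nucleation approximation tracks
#'   the dynamics well.
#' * `"stable_basal_capacity"` (`lambda_init >= mu_crit` and
#'   `mu > mu_crit`): even fully damaged clearance remains supercritical;
#'   toxic mass eventually decays.
#' * `"invasion_regime"` (`lambda_init >= mu_crit > mu`): clearance decays
#'   through the critical value and sigmoidal invasion follows.
#'
#' @inheritParams simulate_invivo
#' @param dspec a [damage_spec()] with size-uniform `mu` and `lambda_init`.
#' @return A regime label (character), with attribute `mu_crit`.
#' @export
classify_regime <- function(dspec, params) {
  stopifnot(inherits(dspec, "damage_spec"))
  if (length(dspec$mu) != 1L || length(dspec$lambda_init) != 1L)
    stop("regime classification requires size-uniform mu and lambda_init",
         call. = FALSE)
  mu_crit <- critical_clearance(params, "constant")
  label <- if (dspec$lambda_init < mu_crit) "subcritical_start"
  else if (dspec$mu > mu_crit) "stable_basal_capacity"
  else "invasion_regime"
  structure(label, mu_crit = mu_crit)
}
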