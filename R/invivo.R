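#' Simulate the single-region in vivo model
#'
#' The in vivo master equations keep the monomer concentration fixed at
#' `m_0` (production balances monomer clearance), saturate secondary
#' nucleation with respect to the aggregate mass
#' (`sigma(M) = K_M / (K_M + M^2)`), and remove size-`i` aggregates at rate
#' `lambda_i` given by a [clearance_spec()]:
#' \deqn{dp_2/dt = -\lambda_2 p_2 + k_n m_0^2 - 2 k_+ m_0 p_2 +
#'   k_2 \sigma(M) m_0^2 M}
#' \deqn{dp_i/dt = -\lambda_i p_i + 2 k_+ m_0 (p_{i-1} - p_i), \quad i > 2.}
#' Primary nucleation is homogeneous here (`k_n m^2`); for seeded runs it is
#' negligible and disabled by default (`include_kn = FALSE`), which makes
#' the aggregate-free state an exact fixed point. Above the critical
#' clearance the trajectory decays to zero; below it, it grows to a peak and
#' relaxes to the nonzero equilibrium (transcritical bifurcation).
#'
#' @inheritParams simulate_invitro
#' @param spec a [clearance_spec()].
#' @param seed numeric vector of initial aggregate concentrations for sizes
#'   `2..N` (padded with zeros); the conventional seeding is
#'   `p_2(0) = m_0 * 1e-4`.
#' @param include_kn include the homogeneous primary nucleation source
#'   `k_n m_0^2`.
#' @param N truncation size (default 300; the equilibrium tail is geometric
#'   with ratio `2 k_+ m_0 / (lambda + 2 k_+ m_0)`, so `N` must be large
#'   enough for the clearance at hand — a runtime tail-mass diagnostic
#'   enforces this).
#' @return An `aggregation_trajectory` (monomer column constant at `m_0`).
#' @export
simulate_invivo <- function(params, spec, seed = NULL, t_end = 1, N = 300,
                            include_kn = FALSE, times = NULL, n_out = 201,
                            rtol = 1e-8, atol = 1e-12 * params$m_0) {
  stopifnot(inherits(spec, "clearance_spec"))
  if (N < 3) stop("truncation size N must be >= 3", call. = FALSE)
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  p0 <- rep(0, N - 1L)
  if (!is.null(seed)) p0[seq_along(seed)] <- seed
  if (all(p0 == 0) && !include_kn)
    warning("zero seed with k_n disabled: the trajectory is identically 0",
            call. = FALSE)
  lam <- clearance_vector(spec, N)
  m0 <- params$m_0
  sizes <- seq(2L, N)
  kn_src <- if (include_kn) params$k_n * m0^2 else 0
  f_el <- 2 * params$k_plus * m0
  deriv <- function(t, p, parms) {
    M <- sum(sizes * p)
    sig <- params$K_M / (params$K_M + M^2)
    nuc2 <- params$k_2 * sig * m0^2 * M
    f <- f_el * p
    f[N - 1L] <- 0
    dp <- -lam * p + c(kn_src + nuc2, rep(0, N - 2L)) +
      c(0, f[-(N - 1L)]) - f
    list(dp)
  }
  sol <- deSolve::ode(y = p0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  sol_full <- cbind(sol[, 1L], m0, sol[, -1L, drop = FALSE])
  build_trajectory(sol_full, params, N, rtol, atol, model = "invivo",
                   extra = list(clearance = spec))
}

#' Simulate the in vivo moment system (constant clearance)
#'
#' For size-independent clearance the in vivo master equations close at the
#' level of the first two moments:
#' \deqn{dP/dt = -\lambda P + k_n m_0^2 + k_2 \sigma(M) m_0^2 M}
#' \deqn{dM/dt = -\lambda M + 2 k_n m_0^2 + 2 k_+ m_0 P +
#'   2 k_2 \sigma(M) m_0^2 M.}
#' Size-dependent clearance does not close the moments (see
#' [simulate_invivo()]); a time-varying scalar `lambda(t)` is supported (the
#' dosing machinery of [simulate_dosing()] builds on it).
#'
#' @inheritParams simulate_invivo
#' @param lambda constant clearance rate, a constant-variant
#'   [clearance_spec()], or a function of time `lambda(t)`.
#' @param P0,M0 initial moments; the conventional dimer seed
#'   `p_2(0) = m_0 * 1e-4` corresponds to `P0 = m_0 * 1e-4`,
#'   `M0 = 2e-4 * m_0`.
#' @return A `moment_trajectory`.
#' @export
simulate_invivo_moments <- function(params, lambda, P0 = params$m_0 * 1e-4,
                                    M0 = 2 * P0, t_end = 1,
                                    include_kn = FALSE, times = NULL,
                                    n_out = 401, rtol = 1e-8,
                                    atol = 1e-12 * params$m_0) {
  lam_fun <- as_lambda_function(lambda)
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  m0 <- params$m_0
  kn_src <- if (include_kn) params$k_n * m0^2 else 0
  deriv <- function(t, y, parms) {
    P <- y[1L]; M <- y[2L]
    lam <- lam_fun(t)
    sig <- params$K_M / (params$K_M + M^2)
    nuc2 <- params$k_2 * sig * m0^2 * M
    list(c(-lam * P + kn_src + nuc2,
           -lam * M + 2 * kn_src + 2 * params$k_plus * m0 * P + 2 * nuc2))
  }
  sol <- deSolve::ode(y = c(P = P0, M = M0), times = times, func = deriv,
                      parms = NULL, method = "vode",
                      rtol = rtol, atol = atol)
  structure(list(time = sol[, 1L], P = sol[, 2L], M = sol[, 3L],
                 m = rep(m0, nrow(sol)),
                 lambda = vapply(sol[, 1L], lam_fun, numeric(1L)),
                 meta = list(model = "invivo_moments", params = params,
                             lambda = lambda, include_kn = include_kn,
                             rtol = rtol, atol = atol, method = "vode")),
            class = "moment_trajectory")
}

as_lambda_function <- function(lambda) {
  if (is.function(lambda)) return(lambda)
  if (inherits(lambda, "clearance_spec")) {
    if (lambda$variant != "constant")
      stop("moment closure requires size-independent clearance; got '",
           lambda$variant, "'", call. = FALSE)
    lam <- lambda$lambda
    return(function(t) lam)
  }
  if (is.numeric(lambda) && length(lambda) == 1L && lambda >= 0)
    return(function(t) lambda)
  stop("`lambda` must be a non-negative number, a constant clearance spec, ",
       "or a function of time", call. = FALSE)
}

#' Nontrivial fixed point of the constant-clearance moment system
#'
#' The moment system with constant clearance has the aggregate-free fixed
#' point and, for `0 < lambda < lambda_crit`, the aggregated state
#' \deqn{M_2 = \frac{\sqrt{K_M(-\lambda^2 + 2\lambda k_2 m_0^2 +
#'   2 k_+ k_2 m_0^3)}}{\lambda}, \quad
#'   P_2 = \frac{\sqrt{K_M(-\lambda^2 + 2\lambda k_2 m_0^2 +
#'   2 k_+ k_2 m_0^3)}}{2(k_+ m_0 + \lambda)}.}
#' The radicand vanishes at the critical clearance (transcritical
#' bifurcation); the asymptotic mass scales as `sqrt(K_M)`.
#'
#' @inheritParams simulate_invivo
#' @param lambda constant clearance rate (> 0).
#' @param N number of sizes for the returned geometric equilibrium table.
#' @return A list of class `fixed_point`: `P_star`, `M_star`, `p_star`
#'   (geometric size table), `exists`, `lambda_crit`.
#' @export
fixed_point_constant <- function(params, lambda, N = 300) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("`lambda` must be a single positive rate", call. = FALSE)
  m0 <- params$m_0
  rad <- params$K_M * (-lambda^2 + 2 * lambda * params$k_2 * m0^2 +
                         2 * params$k_plus * params$k_2 * m0^3)
  lc <- critical_clearance(params, "constant")
  if (rad <= 0)
    return(structure(list(P_star = 0, M_star = 0,
                          p_star = stats::setNames(rep(0, N - 1L), 2:N),
                          exists = FALSE, lambda_crit = lc),
                     class = "fixed_point"))
  M2 <- sqrt(rad) / lambda
  P2 <- sqrt(rad) / (2 * (params$k_plus * m0 + lambda))
  a <- 2 * params$k_plus * m0
  delta <- a / (lambda + a)
  Delta <- (2 - delta) / (1 - delta)^2          # sum of k * delta^(k-2)
  p2 <- M2 / Delta
  p_star <- p2 * delta^(0:(N - 2L))
  structure(list(P_star = P2, M_star = M2,
                 p_star = stats::setNames(p_star, 2:N),
                 exists = TRUE, lambda_crit = lc, delta = delta),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  if (x$exists)
    cat(sprintf(
      "Fixed point: M* = %g, P* = %g (lambda_crit = %g)\n",
      x$M_star, x$P_star, x$lambda_crit))
  else
    cat(sprintf(
      "No nontrivial fixed point (lambda_crit = %g)%s\n", x$lambda_crit,
      if (!is.null(x$failed_condition))
        paste0("; failed condition: ", x$failed_condition) else ""))
  invisible(x)
}

#' Critical clearance rate (transcritical bifurcation point)
#'
#' The clearance level above which the aggregate-free state is stable
#' (healthy region) and below which a nonzero aggregated equilibrium exists
#' (diseased region). Closed forms exist for three clearance variants:
#'
#' * `constant` (`lambda_i = lambda`):
#'   \deqn{\lambda_{crit} = k_2 m_0^2 + \sqrt{k_2 m_0^3 (k_2 m_0 + 2 k_+)},}
#'   the value at which the radicand of the [fixed_point_constant()] mass
#'   vanishes and the leading eigenvalue of the aggregate-free state crosses
#'   zero. (An algebraically inequivalent variant with the factor 2 placed
#'   inside the first summand of the radicand circulates in the literature;
#'   the form used here is the one consistent with the fixed point and with
#'   the numerically observed bifurcation, see [bifurcation_search()].)
#' * `linear_in_size` (`lambda_i = i lambda_0`):
#'   `(k_+ k_2 m_0^3 - 1) / (k_+ m_0 - k_2 m_0^2)`. This printed form is
#'   dimensionally inconsistent (the "- 1" term); it is provided as-is for
#'   reference and [bifurcation_search()] offers a numerical cross-check.
#' * `inverse_size` (`lambda_i = lambda_0 / i`):
#'   `2a(a + 4 k_2 m_0^2)/(a + k_2 m_0^2)` with `a = 2 k_+ m_0`,
#'   approximately `2a` since `a >> k_2 m_0^2`.
#'
#' @inheritParams simulate_invivo
#' @param variant clearance variant; windowed/tabulated have no closed form
#'   and raise an error.
#' @return The critical rate (`lambda` or `lambda_0`, 1/time).
#' @export
#' @examples
#' critical_clearance(abeta_parameters(), "constant")  # ~1.27e4 per hour
critical_clearance <- function(params,
                               variant = c("constant", "linear_in_size",
                                           "inverse_size")) {
  variant <- tryCatch(match.arg(variant),
                      error = function(e)
                        stop("no closed-form critical clearance for ",
                             "variant '", variant[1L], "'", call. = FALSE))
  m0 <- params$m_0; k2 <- params$k_2; kp <- params$k_plus
  switch(variant,
    constant = k2 * m0^2 + sqrt(k2 * m0^3 * (k2 * m0 + 2 * kp)),
    linear_in_size = (kp * k2 * m0^3 - 1) / (kp * m0 - k2 * m0^2),
    inverse_size = {
      a <- 2 * kp * m0
      2 * a * (a + 4 * k2 * m0^2) / (a + k2 * m0^2)
    })
}

#' Equilibrium aggregate size distribution
#'
#' Fixed point of the in vivo master equations for any per-size clearance
#' rule. Sizes above the dimer satisfy the recurrence
#' `p_i* = delta_i p_{i-1}*` with
#' `delta_i = 2 k_+ m_0 / (lambda_i + 2 k_+ m_0)`, so
#' `p_i* = Delta_i p_2*` with `Delta_i` the cumulative product. Writing
#' `Delta = sum(k Delta_k)`, the dimer balance (including the mass
#' saturation of secondary nucleation) solves exactly to
#' \deqn{p_2^* = \frac{\sqrt{K_M}\,\sqrt{k_2 m_0^2 \Delta - \lambda_2 -
#'   2 k_+ m_0}}{\Delta\,\sqrt{\lambda_2 + 2 k_+ m_0}}.}
#' A fixed point exists iff (C1) `Delta_i -> 0`, (C2) `Delta` converges, and
#' (C3) the radicand above is positive.
#'
#' With `boundary = "reflecting"` the computation mirrors the reflecting
#' truncation of the simulator (last size balance
#' `p_N* = (2 k_+ m_0 / lambda_N) p_{N-1}*`), so it is the exact steady
#' state of [simulate_invivo()] at the same `N`. With
#' `boundary = "infinite"` the sum `Delta` is completed with the analytic
#' geometric tail beyond `N` (exact whenever `lambda_i` is constant beyond
#' some size, i.e. all variants except `linear_in_size`/`inverse_size`, for
#' which the tail beyond `N` must be negligible).
#'
#' @inheritParams simulate_invivo
#' @param N truncation size of the reported table.
#' @param boundary `"reflecting"` (match the truncated simulator) or
#'   `"infinite"` (analytic tail completion).
#' @return A `fixed_point` list: `P_star`, `M_star`, `p_star` (sizes
#'   `2..N`), `exists`, `lambda_crit` (constant variant only, else `NA`),
#'   `conditions` (C1-C3 diagnostics), `Delta`.
#' @export
equilibrium_distribution <- function(params, spec, N = 300,
                                     boundary = c("reflecting", "infinite")) {
  stopifnot(inherits(spec, "clearance_spec"))
  boundary <- match.arg(boundary)
  if (N < 4) stop("N must be >= 4", call. = FALSE)
  m0 <- params$m_0
  a <- 2 * params$k_plus * m0
  lam <- clearance_vector(spec, N)
  sizes <- seq(2L, N)
  delta <- a / (lam + a)                    # delta_i for i = 2..N (delta_2 unused)
  Delta_i <- c(1, cumprod(delta[-1L]))      # Delta_i for i = 2..N
  tail_sum <- 0
  failed <- NULL
  if (boundary == "reflecting") {
    if (lam[N - 1L] <= 0)
      stop("reflecting truncated system has no steady state when ",
           "lambda_N = 0", call. = FALSE)
    Delta_i[N - 1L] <- Delta_i[N - 2L] * a / lam[N - 1L]
  } else {
    dinf <- delta[N - 1L]
    # geometric completion: Delta_k = Delta_N * dinf^(k-N) for k > N, so
    # sum_{k>N} k Delta_k = Delta_N * (N d/(1-d) + d/(1-d)^2)
    tail_sum <- Delta_i[N - 1L] * (N * dinf / (1 - dinf) +
                                     dinf / (1 - dinf)^2)
    if (spec$variant %in% c("linear_in_size", "inverse_size") &&
        tail_sum > 1e-8 * sum(sizes * Delta_i))
      warning("size distribution tail beyond N is not negligible for this ",
              "clearance variant; increase N", call. = FALSE)
  }
  Delta <- sum(sizes * Delta_i) + tail_sum
  # C1/C2 diagnostics on the computed table
  c1 <- Delta_i[N - 1L] < 1e-6 * max(Delta_i)
  c2 <- N * Delta_i[N - 1L] < 1e-4 * Delta
  disc <- params$k_2 * m0^2 * Delta - lam[1L] - a
  c3 <- disc > 0
  if (!c3) failed <- "C3 (dimer balance radicand non-positive)"
  lc <- if (spec$variant == "constant")
    critical_clearance(params, "constant") else NA_real_
  if (!c3) {
    return(structure(list(P_star = 0, M_star = 0,
                          p_star = stats::setNames(rep(0, N - 1L), sizes),
                          exists = FALSE, lambda_crit = lc,
                          conditions = list(C1 = c1, C2 = c2, C3 = c3),
                          Delta = Delta, failed_condition = failed),
                     class = "fixed_point"))
  }
  p2 <- sqrt(params$K_M) * sqrt(disc) / (Delta * sqrt(lam[1L] + a))
  p_star <- p2 * Delta_i
  structure(list(P_star = sum(p_star) +
                   if (boundary == "infinite")
                     p_star[N - 1L] * delta[N - 1L] / (1 - delta[N - 1L])
                   else 0,
                 M_star = Delta * p2,
                 p_star = stats::setNames(p_star, sizes),
                 exists = TRUE, lambda_crit = lc,
                 conditions = list(C1 = c1, C2 = c2, C3 = c3),
                 Delta = Delta),
            class = "fixed_point")
}

#' Peak toxic mass and characteristic timescales of a trajectory
#'
#' For a subcritical seeded run the toxic mass grows to a maximum
#' `M_max` at time `tau_1` and then relaxes; `tau_2` is the first time
#' after the peak at which `|M - M_2| < epsilon` (with `M_2` the
#' equilibrium mass).
#'
#' @param traj an `aggregation_trajectory` or `moment_trajectory`.
#' @param epsilon relaxation tolerance defining `tau_2`.
#' @param M2 equilibrium mass; by default computed from the trajectory's
#'   constant clearance via [fixed_point_constant()].
#' @return A list `(M_max, tau1, tau2)`; all `NA` when the trajectory has
#'   no interior peak, `tau2` `NA` when relaxation is not reached.
#' @export
peak_and_timescales <- function(traj, epsilon, M2 = NULL) {
  M <- traj$M; t <- traj$time
  k <- which.max(M)
  if (k == 1L || k == length(M))
    return(list(M_max = NA_real_, tau1 = NA_real_, tau2 = NA_real_))
  if (is.null(M2)) {
    lam <- traj$meta$lambda
    if (inherits(traj, "aggregation_trajectory") &&
        !is.null(traj$clearance) && traj$clearance$variant == "constant")
      lam <- traj$clearance$lambda
    if (inherits(lam, "clearance_spec") && lam$variant == "constant")
      lam <- lam$lambda
    if (is.null(lam) || !is.numeric(lam))
      stop("supply `M2` (equilibrium mass) for this trajectory",
           call. = FALSE)
    M2 <- fixed_point_constant(traj$meta$params, lam)$M_star
  }
  after <- which(t > t[k] & abs(M - M2) < epsilon)
  list(M_max = M[k], tau1 = t[k],
       tau2 = if (length(after)) t[after[1L]] else NA_real_)
}

#' Equilibrium toxic mass under windowed (size-targeted) clearance
#'
#' Drug-enhanced clearance `lambda_drug` applied on the size window
#' `n0 <= i <= n1` on top of background clearance `lambda_a`. Computed from
#' [equilibrium_distribution()] with the windowed clearance rule and
#' analytic tail completion; targeting smaller aggregates lowers the
#' equilibrium toxic mass the most.
#'
#' @inheritParams simulate_invivo
#' @param lambda_a background clearance rate.
#' @param lambda_drug clearance increment inside the window.
#' @param n0,n1 inclusive size window, `2 <= n0 <= n1`.
#' @param N table truncation (the mass itself includes the analytic tail).
#' @return The equilibrium toxic mass `M_star` (0 when no aggregated state
#'   exists).
#' @export
interval_mass_reduction <- function(params, lambda_a, lambda_drug, n0, n1,
                                    N = max(300, n1 + 10)) {
  sp <- clearance_spec("windowed", lambda_a = lambda_a,
                       lambda_drug = lambda_drug, n0 = n0, n1 = n1)
  eq <- equilibrium_distribution(params, sp, N = N, boundary = "infinite")
  eq$M_star
}

#' Compare equilibrium mass removed by targeting different size intervals
#'
#' For a constant background clearance `lambda`, the equilibrium mass
#' residing in a size interval `I` is `sum_{k in I} k Delta_k p_2*` with the
#' geometric `Delta_k` of the untreated system; this is the mass a clearance
#' drug targeting `I` acts upon. Removal of lower intervals reduces the
#' total equilibrium toxic mass more, because the geometric size
#' distribution concentrates mass at small sizes when `2 k_+ m_0 >> lambda`.
#'
#' @inheritParams simulate_invivo
#' @param lambda constant background clearance (subcritical).
#' @param intervals list of inclusive integer ranges `c(lo, hi)`,
#'   non-overlapping, each with `lo >= 2`.
#' @return Named numeric vector of per-interval equilibrium masses, in the
#'   order given (names `"lo-hi"`).
#' @export
compare_interval_targets <- function(params, lambda, intervals) {
  iv <- lapply(intervals, function(x) {
    if (length(x) != 2L || x[1L] < 2 || x[2L] < x[1L])
      stop("each interval must be c(lo, hi) with 2 <= lo <= hi",
           call. = FALSE)
    as.integer(x)
  })
  n <- length(iv)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (iv[[i]][1L] <= iv[[j]][2L] && iv[[j]][1L] <= iv[[i]][2L] &&
          !identical(iv[[i]], iv[[j]]))
        stop("intervals overlap: ", paste(iv[[i]], collapse = "-"), " and ",
             paste(iv[[j]], collapse = "-"), call. = FALSE)
    }
  }
  fp <- fixed_point_constant(params, lambda)
  if (!fp$exists)
    stop("no aggregated equilibrium at lambda = ", lambda, call. = FALSE)
  a <- 2 * params$k_plus * params$m_0
  delta <- a / (lambda + a)
  p2 <- fp$M_star / ((2 - delta) / (1 - delta)^2)
  mass_in <- function(lo, hi) {
    k <- seq(lo, hi)
    p2 * sum(k * delta^(k - 2))
  }
  stats::setNames(vapply(iv, function(x) mass_in(x[1L], x[2L]), numeric(1L)),
                  vapply(iv, paste, character(1L), collapse = "-"))
}

#' Locate the clearance bifurcation point empirically
#'
#' Bisection on the constant clearance rate over simulated outcomes of the
#' moment system: a tiny dimer seed either grows (subcritical clearance) or
#' decays (supercritical). This is a self-consistency check on
#' [critical_clearance()] that does not use any closed form.
#'
#' @inheritParams simulate_invivo
#' @param lower,upper initial bracket (must straddle the transition).
#' @param tol relative bracket width at which to stop.
#' @param t_probe integration horizon per probe.
#' @return The midpoint estimate of the critical clearance rate.
#' @export
bifurcation_search <- function(params, lower = NULL, upper = NULL,
                               tol = 1e-4, t_probe = 1) {
  guess <- critical_clearance(params, "constant")
  if (is.null(lower)) lower <- guess / 2
  if (is.null(upper)) upper <- guess * 2
  seed <- params$m_0 * 1e-8
  grows <- function(lam) {
    tr <- simulate_invivo_moments(params, lam, P0 = seed, M0 = 2 * seed,
                                  t_end = t_probe, n_out = 11)
    tr$M[length(tr$M)] > 2 * tr$M[1L]
  }
  if (!grows(lower) || grows(upper))
    stop("bracket [lower, upper] does not straddle the bifurcation",
         call. = FALSE)
  while ((upper - lower) > tol * upper) {
    mid <- (lower + upper) / 2
    if (grows(mid)) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}
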