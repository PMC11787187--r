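#' Pharmacodynamic drug effect on aggregation kinetics and clearance
#'
#' Monoclonal antibodies act on the model in two ways: inhibition of
#' secondary nucleation (a multiplier `delta_k` in `[0, 1]` on `k_2`; e.g.
#' the strongest reported aducanumab dose corresponds to a 69% reduction,
#' `delta_k = 0.31`) and antibody-mediated removal, a clearance increment
#' `lambda_drug = L * C_p` proportional to the plasma concentration `C_p`
#' with an antibody-specific constant `L`.
#'
#' @param delta_k multiplier on the secondary nucleation rate, in `[0, 1]`.
#' @param lambda_drug direct clearance increment (1/time); alternatively
#'   supply `L` and `C_p`.
#' @param L clearance-per-concentration constant.
#' @param C_p plasma drug concentration.
#' @return An object of class `drug_effect` with fields `delta_k` and
#'   `lambda_drug`.
#' @export
drug_effect <- function(delta_k = 1, lambda_drug = NULL, L = NULL,
                        C_p = NULL) {
  if (!is.numeric(delta_k) || length(delta_k) != 1L || delta_k < 0 ||
      delta_k > 1)
    stop("`delta_k` must be a single number in [0, 1]", call. = FALSE)
  if (is.null(lambda_drug))
    lambda_drug <- if (!is.null(L) && !is.null(C_p)) L * C_p else 0
  if (lambda_drug < 0)
    stop("`lambda_drug` must be non-negative", call. = FALSE)
  structure(list(delta_k = delta_k, lambda_drug = lambda_drug),
            class = "drug_effect")
}

#' Apply a drug effect to a parameter set (and clearance rule)
#'
#' Substitutes the inhibited secondary nucleation rate
#' `k_2~ = delta_k * k_2` and reports the uniform clearance increment every
#' size receives; downstream quantities (critical clearance, fixed points)
#' are recomputed from the returned parameters.
#'
#' @inheritParams simulate_invivo
#' @param effect a [drug_effect()].
#' @param spec optional [clearance_spec()] to which the increment is added.
#' @return A list with `params` (modified), `lambda_drug` (increment) and,
#'   when `spec` was given, `clearance` (the shifted spec).
#' @export
apply_drug <- function(params, effect, spec = NULL) {
  stopifnot(inherits(effect, "drug_effect"))
  params$k_2 <- effect$delta_k * params$k_2
  out <- list(params = params, lambda_drug = effect$lambda_drug)
  if (!is.null(spec))
    out$clearance <- shift_clearance(spec, effect$lambda_drug)
  out
}

#' Ratio of drugged to undrugged critical clearance across inhibition levels
#'
#' For each secondary-nucleation multiplier `delta_k` in the grid, the
#' critical clearance with `k_2~ = delta_k * k_2` divided by the untreated
#' value, for each requested clearance variant with a closed form. The
#' ratio is 1 at `delta_k = 1` and decreases as inhibition strengthens.
#'
#' @inheritParams simulate_invivo
#' @param delta_k numeric vector of multipliers in `(0, 1]`.
#' @param variants clearance variants to evaluate.
#' @return A data frame with columns `delta_k`, `variant`, `ratio`.
#' @export
critical_clearance_ratio_curve <- function(params, delta_k,
                                           variants = c("constant",
                                                        "linear_in_size",
                                                        "inverse_size")) {
  if (any(delta_k <= 0 | delta_k > 1))
    stop("`delta_k` values must lie in (0, 1]", call. = FALSE)
  rows <- lapply(variants, function(v) {
    base <- critical_clearance(params, v)
    ratio <- vapply(delta_k, function(dk) {
      p <- params
      p$k_2 <- dk * p$k_2
      critical_clearance(p, v) / base
    }, numeric(1L))
    data.frame(delta_k = delta_k, variant = v, ratio = ratio)
  })
  do.call(rbind, rows)
}

#' Periodic dosing regime
#'
#' Equally spaced doses with single-exponential elimination produce the
#' periodic clearance profile
#' \deqn{\lambda(t) = \lambda_{drug}\, e^{-A \,(t \bmod B)} + \lambda_a,}
#' where `A` is the elimination rate of the drug from the brain, `B` the
#' inter-dose interval, `lambda_a` the natural background clearance and
#' `lambda_drug` the peak clearance increment per dose (proportional to the
#' dose). `B = 0` denotes the constant-supply limit
#' (`lambda(t) = lambda_a + lambda_drug`). The integrated clearance
#' increment over the trial horizon `t_max` is the dose-toxicity budget
#' `C_max` (see [integrated_dose()]).
#'
#' @param lambda_drug peak clearance increment per dose (1/time).
#' @param A drug elimination rate (1/time).
#' @param B inter-dose interval (time); `0` for constant supply.
#' @param lambda_a background clearance (1/time).
#' @param t_max trial horizon (time).
#' @return An object of class `dosing_regime`; field `C_max` holds the
#'   integrated dose.
#' @export
dosing_regime <- function(lambda_drug, A = 1, B = 1, lambda_a = 10,
                          t_max = 28) {
  if (B < 0) stop("`B` must be non-negative", call. = FALSE)
  if (any(c(lambda_drug, A, lambda_a) < 0))
    stop("rates must be non-negative", call. = FALSE)
  if (t_max <= 0) stop("`t_max` must be positive", call. = FALSE)
  r <- structure(list(lambda_drug = lambda_drug, A = A, B = B,
                      lambda_a = lambda_a, t_max = t_max),
                 class = "dosing_regime")
  r$C_max <- integrated_dose(r)
  r
}

#' @export
print.dosing_regime <- function(x, ...) {
  cat(sprintf(
    "Dosing regime: lambda_drug = %g, A = %g, B = %s, lambda_a = %g, t_max = %g (C_max = %g)\n",
    x$lambda_drug, x$A,
    if (x$B == 0) "0 (constant supply)" else format(x$B), x$lambda_a,
    x$t_max, x$C_max))
  invisible(x)
}

#' Evaluate the dosing clearance profile
#'
#' @param regime a [dosing_regime()].
#' @param t time (vector allowed), `>= 0`.
#' @return Clearance rate `lambda(t)`.
#' @export
dosing_profile <- function(regime, t) {
  stopifnot(inherits(regime, "dosing_regime"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (regime$B == 0) return(rep(regime$lambda_a + regime$lambda_drug,
                                length(t)))
  regime$lambda_drug * exp(-regime$A * (t %% regime$B)) + regime$lambda_a
}

#' Integrated clearance increment of a dosing regime
#'
#' The dose budget
#' \deqn{C_{max} = \int_0^{t_{max}} \lambda_{drug}\, e^{-A(t \bmod B)}\,dt
#'   = \frac{\lambda_{drug}}{A}\left(n(1 - e^{-AB}) + 1 - e^{-Ar}\right)}
#' with `t_max = n B + r`, `0 <= r < B`; in the constant-supply limit
#' `B -> 0` this tends to `lambda_drug * t_max`.
#'
#' @param regime a [dosing_regime()].
#' @return The integrated dose `C_max`.
#' @export
integrated_dose <- function(regime) {
  stopifnot(inherits(regime, "dosing_regime"))
  if (regime$B == 0 || regime$A == 0)
    return(regime$lambda_drug * regime$t_max)
  n <- floor(regime$t_max / regime$B)
  r <- regime$t_max - n * regime$B
  regime$lambda_drug / regime$A *
    (n * (1 - exp(-regime$A * regime$B)) + 1 - exp(-regime$A * r))
}

#' Simulate the moment system under a periodic dosing regime
#'
#' Integrates the constant-monomer moment system with the time-varying
#' clearance `lambda(t)` of [dosing_profile()], cycle by cycle (each dose
#' restarts the integrator at the profile discontinuity), until a periodic
#' steady state is reached: successive cycle maxima of `M` agree to a
#' relative tolerance, after at least `min_cycles` cycles. The final cycle
#' is re-integrated on a fine grid for averaging.
#'
#' @inheritParams simulate_invivo_moments
#' @param regime a [dosing_regime()].
#' @param ss_tol relative cycle-to-cycle tolerance on the maximum of `M`.
#' @param min_cycles,max_cycles bounds on the number of cycles integrated.
#' @param n_cycle output points per cycle (final cycle uses `4 * n_cycle`).
#' @return A list of class `dosing_simulation`: `cycle` (fine
#'   `moment_trajectory` over the final cycle, time measured from the last
#'   dose), `converged`, `n_cycles`, `regime`, and the burn-in cycle maxima
#'   `cycle_max`.
#' @export
simulate_dosing <- function(params, regime, P0 = params$m_0 * 1e-4,
                            M0 = 2 * P0, include_kn = FALSE, ss_tol = 1e-6,
                            min_cycles = 20, max_cycles = 400,
                            n_cycle = 81, rtol = 1e-8,
                            atol = 1e-12 * params$m_0) {
  stopifnot(inherits(regime, "dosing_regime"))
  if (regime$B == 0) {
    lam <- regime$lambda_a + regime$lambda_drug
    tr <- simulate_invivo_moments(params, lam, P0 = P0, M0 = M0,
                                  t_end = 5, include_kn = include_kn,
                                  n_out = 501, rtol = rtol, atol = atol)
    n <- length(tr$time)
    converged <- abs(tr$M[n] - tr$M[n - 50L]) <= ss_tol * max(tr$M[n], atol)
    return(structure(list(cycle = tr, converged = converged, n_cycles = 0L,
                          regime = regime,
                          cycle_max = max(tr$M[(n - 50L):n])),
                     class = "dosing_simulation"))
  }
  lam_cycle <- function(t)
    regime$lambda_drug * exp(-regime$A * t) + regime$lambda_a
  y <- c(P0, M0)
  cyc_max <- numeric(0)
  converged <- FALSE
  k <- 0L
  while (k < max_cycles) {
    k <- k + 1L
    tr <- simulate_invivo_moments(params, lam_cycle, P0 = y[1L],
                                  M0 = y[2L], t_end = regime$B,
                                  include_kn = include_kn,
                                  n_out = n_cycle, rtol = rtol, atol = atol)
    n <- length(tr$time)
    y <- c(tr$P[n], tr$M[n])
    cyc_max <- c(cyc_max, max(tr$M))
    if (k >= min_cycles) {
      prev <- cyc_max[k - 1L]
      if (abs(cyc_max[k] - prev) <= ss_tol * max(cyc_max[k], atol)) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("no periodic steady state within ", max_cycles,
            " cycles (last relative change ",
            format(abs(diff(utils::tail(cyc_max, 2))) /
                     utils::tail(cyc_max, 1L)), ")", call. = FALSE)
  n_fine <- max(4L * n_cycle, 2L * ceiling(250 * regime$B)) + 1L
  fine <- simulate_invivo_moments(params, lam_cycle, P0 = y[1L],
                                  M0 = y[2L], t_end = regime$B,
                                  include_kn = include_kn,
                                  n_out = n_fine,
                                  rtol = rtol, atol = atol)
  structure(list(cycle = fine, converged = converged, n_cycles = k,
                 regime = regime, cycle_max = cyc_max),
            class = "dosing_simulation")
}

#' @export
print.dosing_simulation <- function(x, ...) {
  cat(sprintf(
    "Dosing simulation: %s after %d cycles; cycle-averaged M = %g\n",
    if (x$converged) "periodic steady state" else "NOT converged",
    x$n_cycles, cycle_average_mass(x)))
  invisible(x)
}

#' Cycle-averaged toxic mass at the periodic steady state
#'
#' Time-average of `M` over one inter-dose period at the periodic steady
#' state (trapezoidal rule on the fine final-cycle grid, checked against a
#' coarsened grid to a relative tolerance of `1e-4`).
#'
#' @param sim a [simulate_dosing()] result.
#' @param require_converged error if the simulation did not reach a
#'   periodic steady state.
#' @return The average toxic mass `M_bar`.
#' @export
cycle_average_mass <- function(sim, require_converged = TRUE) {
  stopifnot(inherits(sim, "dosing_simulation"))
  if (require_converged && !sim$converged)
    stop("periodic steady state not reached; cannot average", call. = FALSE)
  tr <- sim$cycle
  if (sim$regime$B == 0) return(tr$M[length(tr$M)])
  trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) +
                                           utils::tail(y, -1)) / 2)
  full <- trapz(tr$time, tr$M) / diff(range(tr$time))
  half_idx <- seq(1L, length(tr$time), by = 2L)
  half <- trapz(tr$time[half_idx], tr$M[half_idx]) /
    diff(range(tr$time))
  if (abs(full - half) > 1e-4 * abs(full))
    warning("cycle average not resolved to 1e-4; increase `n_cycle`",
            call. = FALSE)
  full
}

#' Optimize the dosing regime under an integrated-dose budget
#'
#' Minimizes the cycle-averaged toxic mass over the inter-dose interval `B`
#' and peak increment `lambda_drug`, subject to the budget
#' `integrated_dose = C_max` and box bounds (`0.2 < B < t_max`,
#' `0.2 < lambda_drug < 80` by default). Since the integrated dose is
#' linear in `lambda_drug`, the constraint fixes `lambda_drug` for each `B`
#' on a deterministic grid; the feasible profile of `M_bar` against `B` is
#' returned along with the constrained minimizer. More frequent dosing
#' (smaller `B`) is always at least as good, so the optimum sits at the
#' smallest admissible `B`.
#'
#' @inheritParams simulate_invivo
#' @param C_max integrated-dose budget.
#' @param lambda_a background clearance.
#' @param A drug elimination rate.
#' @param t_max trial horizon.
#' @param B_bounds,lambda_bounds open box bounds on `B` and `lambda_drug`.
#' @param n_B number of grid points in `B`.
#' @param ... passed to [simulate_dosing()].
#' @return A list of class `regime_optimum`: `B`, `lambda_drug`, `M_bar`
#'   (the minimizer) and `surface` (data frame over the `B` grid with the
#'   budget-matching `lambda_drug`, `M_bar`, `feasible`).
#' @export
optimize_regime <- function(params, C_max, lambda_a = 10, A = 1,
                            t_max = 28, B_bounds = c(0.2, t_max),
                            lambda_bounds = c(0.2, 80), n_B = 15, ...) {
  B_grid <- seq(B_bounds[1L], min(B_bounds[2L], t_max),
                length.out = n_B)
  lam_for_B <- vapply(B_grid, function(B) {
    unit <- integrated_dose(dosing_regime(1, A = A, B = B,
                                          lambda_a = lambda_a,
                                          t_max = t_max))
    C_max / unit
  }, numeric(1L))
  feasible <- lam_for_B > lambda_bounds[1L] & lam_for_B < lambda_bounds[2L]
  if (!any(feasible)) {
    stop("budget C_max = ", C_max, " not achievable within bounds for any ",
         "B in [", B_bounds[1L], ", ", B_bounds[2L], "]; achievable ",
         "lambda_drug range on the grid: [",
         format(min(lam_for_B)), ", ", format(max(lam_for_B)), "]",
         call. = FALSE)
  }
  M_bar <- rep(NA_real_, n_B)
  for (i in which(feasible)) {
    sim <- simulate_dosing(params,
                           dosing_regime(lam_for_B[i], A = A, B = B_grid[i],
                                         lambda_a = lambda_a,
                                         t_max = t_max), ...)
    M_bar[i] <- cycle_average_mass(sim)
  }
  best <- which.min(replace(M_bar, !feasible, Inf))
  structure(list(B = B_grid[best], lambda_drug = lam_for_B[best],
                 M_bar = M_bar[best],
                 surface = data.frame(B = B_grid,
                                      lambda_drug = lam_for_B,
                                      M_bar = M_bar,
                                      feasible = feasible)),
            class = "regime_optimum")
}

#' @export
print.regime_optimum <- function(x, ...) {
  cat(sprintf(
    "Optimal dosing regime: B = %g, lambda_drug = %g, M_bar = %g\n",
    x$B, x$lambda_drug, x$M_bar))
  invisible(x)
}
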