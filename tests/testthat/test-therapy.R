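test_that("drug effects modify kinetics and clearance as specified", {
  eff0 <- drug_effect(delta_k = 1, lambda_drug = 0)
  out0 <- apply_drug(p_uM, eff0)
  expect_equal(out0$params, p_uM)                       # identity
  expect_equal(out0$lambda_drug, 0)

  eff <- drug_effect(delta_k = 0.5, lambda_drug = 7)
  out <- apply_drug(p_uM, eff, spec = clearance_spec("constant",
                                                     lambda = 10))
  expect_equal(out$params$k_2, 105)
  expect_equal(out$clearance$lambda, 17)
  # drug-reduced critical clearance (frozen direct evaluation, checked
  # against the empirical bifurcation of the drugged system)
  drugged_crit <- critical_clearance(out$params, "constant")
  expect_equal(drugged_crit, 8534.007, tolerance = 1e-6)
  expect_equal(bifurcation_search(out$params, tol = 1e-4), drugged_crit,
               tolerance = 0.005)
  # lambda_drug from plasma concentration
  expect_equal(drug_effect(delta_k = 1, L = 2, C_p = 3)$lambda_drug, 6)
  expect_error(drug_effect(delta_k = 1.2), "\\[0, 1\\]")
  expect_error(drug_effect(delta_k = 0.5, lambda_drug = -1),
               "non-negative")
})

test_that("critical-clearance ratio falls with stronger inhibition", {
  grid <- c(0.1, 0.25, 0.5, 0.75, 1)
  rc <- critical_clearance_ratio_curve(p_uM, grid)
  for (v in unique(rc$variant)) {
    r <- rc$ratio[rc$variant == v]
    expect_equal(r[length(r)], 1)
    expect_true(all(diff(r) > 0))   # monotone in delta_k, so < 1 below 1
  }
  expect_equal(rc$ratio[rc$variant == "constant" & rc$delta_k == 0.5],
               8534.007 / 12705.36, tolerance = 1e-4)
  expect_error(critical_clearance_ratio_curve(p_uM, c(0, 0.5)), "\\(0, 1\\]")
})

test_that("dosing profile is periodic with the stated extremes", {
  reg <- dosing_regime(lambda_drug = 40, A = 1, B = 2, lambda_a = 10,
                       t_max = 28)
  expect_equal(dosing_profile(reg, 0), 50)
  expect_equal(dosing_profile(reg, 2), 50)               # periodic
  expect_equal(dosing_profile(reg, 1.999999), 10 + 40 * exp(-2),
               tolerance = 1e-4)
  tt <- seq(0, 10, by = 0.01)
  expect_equal(dosing_profile(reg, tt), dosing_profile(reg, tt + 2))
  zero <- dosing_regime(0, A = 1, B = 2, lambda_a = 10)
  expect_equal(dosing_profile(zero, tt), rep(10, length(tt)))
  expect_error(dosing_regime(1, B = -1), "non-negative")
  expect_error(dosing_profile(reg, -1), "non-negative")
})

test_that("integrated dose matches quadrature and its limits", {
  reg <- dosing_regime(lambda_drug = 5.6, A = 1, B = 1, lambda_a = 10,
                       t_max = 28)
  expect_equal(integrated_dose(reg), 99.1165, tolerance = 1e-5)
  # numerical quadrature oracle, including a partial final cycle
  for (tm in c(28, 10.4)) {
    r <- dosing_regime(5.6, A = 1.3, B = 3, lambda_a = 10, t_max = tm)
    quad <- stats::integrate(function(t) 5.6 * exp(-1.3 * (t %% 3)),
                             0, tm, subdivisions = 2000,
                             stop.on.error = FALSE)$value
    expect_equal(integrated_dose(r), quad, tolerance = 1e-5)
  }
  # constant-supply limit B -> 0 and instant-elimination limit A -> inf
  expect_equal(integrated_dose(dosing_regime(100 / 28, A = 1, B = 0,
                                             t_max = 28)), 100)
  small_B <- integrated_dose(dosing_regime(2, A = 1, B = 1e-5, t_max = 28))
  expect_equal(small_B, 2 * 28, tolerance = 1e-4)
  expect_lt(integrated_dose(dosing_regime(2, A = 1e5, B = 1, t_max = 28)),
            1e-3)
})

test_that("periodic steady state responds to the dose as expected", {
  # no drug: plain relaxation to the background equilibrium
  s0 <- simulate_dosing(p_uM, dosing_regime(0, A = 1, B = 2,
                                            lambda_a = 10))
  expect_equal(cycle_average_mass(s0),
               fixed_point_constant(p_uM, 10)$M_star, tolerance = 1e-4)
  # increasing the dose lowers the peak and widens the swing
  runs <- lapply(c(2, 5, 10), function(ld)
    simulate_dosing(p_uM, dosing_regime(ld, A = 1, B = 2, lambda_a = 10)))
  peaks <- vapply(runs, function(s) max(s$cycle$M), numeric(1))
  ranges <- vapply(runs, function(s) diff(range(s$cycle$M)), numeric(1))
  expect_true(all(diff(peaks) < 0))
  expect_true(all(diff(ranges) > 0))
  expect_true(all(vapply(runs, `[[`, logical(1), "converged")))
  # away from the dose discontinuity the mass tracks the instantaneous
  # equilibrium M2(lambda(t)) (quasi-static regime)
  s <- runs[[2]]
  late <- s$cycle$time > 1
  M2t <- vapply(s$cycle$time[late], function(t)
    fixed_point_constant(p_uM, 10 + 5 * exp(-t))$M_star, numeric(1))
  expect_lt(max(abs(s$cycle$M[late] - M2t) / M2t), 0.05)
})

test_that("cycle averages reproduce the dosing-strategy comparisons", {
  const <- simulate_dosing(p_uM, dosing_regime(100 / 28, A = 1, B = 0,
                                               lambda_a = 10, t_max = 28))
  daily <- simulate_dosing(p_uM, dosing_regime(5.6, A = 1, B = 1,
                                               lambda_a = 10, t_max = 28))
  weekly <- simulate_dosing(p_uM, dosing_regime(25, A = 1, B = 7,
                                                lambda_a = 10, t_max = 28))
  m_const <- cycle_average_mass(const)
  m_daily <- cycle_average_mass(daily)
  m_weekly <- cycle_average_mass(weekly)
  # ordering: spacing doses out costs toxic mass, at similar total dose
  expect_lt(m_const, m_daily)
  expect_lt(m_daily, m_weekly)
  # wider spacing raises the variance around the average
  expect_lt(diff(range(daily$cycle$M)), diff(range(weekly$cycle$M)))
  # the B -> 0 limit agrees with the constant-clearance fixed point
  expect_equal(m_const,
               fixed_point_constant(p_uM, 10 + 100 / 28)$M_star,
               tolerance = 0.01)
})

test_that("budget-constrained optimization picks the most frequent dosing", {
  opt <- optimize_regime(p_uM, C_max = 100, n_B = 8)
  expect_equal(opt$B, 0.2)                        # smallest admissible B
  feas <- opt$surface[opt$surface$feasible, ]
  expect_equal(feas$M_bar[which.min(feas$B)], min(feas$M_bar),
               tolerance = 1e-9)
  # the average varies weakly along the fixed-budget contour: a 14-fold
  # swing in lambda_drug moves it by well under a third
  expect_lt(diff(range(feas$M_bar)) / min(feas$M_bar), 0.3)
  # doubling the budget strictly lowers the optimal average
  opt2 <- optimize_regime(p_uM, C_max = 200, n_B = 8)
  expect_lt(opt2$M_bar, opt$M_bar)
  # infeasible budget reports the achievable range
  expect_error(optimize_regime(p_uM, C_max = 1e6, n_B = 5), "achievable")
})

test_that("average toxic mass has diminishing returns in dose and interval", {
  # non-increasing in lambda_drug at fixed B
  mb <- vapply(c(5, 20, 60), function(ld)
    cycle_average_mass(simulate_dosing(p_uM,
      dosing_regime(ld, A = 1, B = 2, lambda_a = 10))), numeric(1))
  expect_true(all(diff(mb) < 0))
  # diminishing returns: per-unit-dose gain shrinks at higher doses
  expect_lt(abs(mb[3] - mb[2]) / 40, abs(mb[2] - mb[1]) / 15)
  # shrinking B at fixed lambda_drug lowers the average
  mbB <- vapply(c(7, 2, 0.5), function(B)
    cycle_average_mass(simulate_dosing(p_uM,
      dosing_regime(20, A = 1, B = B, lambda_a = 10))), numeric(1))
  expect_true(all(diff(mbB) < 0))
})
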