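test_that("master-equation right-hand side has the printed structure", {
  N <- 50
  # source-only: empty system nucleates dimers from the constant source
  st0 <- aggregate_state(m = 0, p = rep(0, N - 1))
  d0 <- rhs_invitro(st0, p_uM)
  expect_equal(d0$m, -2 * p_uM$k_n)
  expect_equal(d0$p[1], p_uM$k_n)
  expect_equal(d0$p[-1], rep(0, N - 2))

  # pure elongation shift: a single populated size feeds the next one up
  p5 <- rep(0, N - 1); p5[4] <- 1e-3   # size 5
  st <- aggregate_state(m = 2, p = p5)
  d <- rhs_invitro(st, inert_params())
  expect_equal(d$p[4], -2 * inert_params()$k_plus * 2 * 1e-3)
  expect_equal(d$p[5], +2 * inert_params()$k_plus * 2 * 1e-3)

  # reflecting truncation conserves total mass exactly, for random states
  set.seed(11)
  for (k in 1:20) {
    st <- aggregate_state(m = runif(1, 0, 3),
                          p = runif(N - 1, 0, 1e-3))
    d <- rhs_invitro(st, p_uM)
    total <- d$m + sum(seq(2, N) * d$p)
    scale <- abs(d$m) + sum(abs(d$p))
    expect_lt(abs(total), 1e-12 * max(scale, 1))
  }
})

test_that("size-resolved in vitro run conserves mass and saturates at m0", {
  m0 <- 0.003   # uM units; keeps the aggregate-size front inside N
  tr <- suppressWarnings(simulate_invitro(p_uM, m0 = m0, t_end = 8,
                                          N = 400))
  expect_lte(max(abs(tr$m + tr$M - m0)) / m0, 1e-6)
  expect_true(all(diff(tr$M) > -1e-9 * m0))           # monotone growth
  expect_equal(tr$M[length(tr$M)], m0, tolerance = 0.01)
  expect_equal(tr$meta$N, 400)
  expect_equal(tr$meta$rtol, 1e-8)

  # zero-kinetics fixed point
  z <- inert_params()
  trz <- simulate_invitro(z, m0 = 1, t_end = 1, N = 10)
  expect_equal(max(trz$M), 0)

  # reference concentration needs a much larger truncation: diagnosed
  expect_error(simulate_invitro(p_uM, t_end = 2, N = 100),
               "truncation overflow")
})

test_that("moment closure matches the size-resolved system", {
  m0 <- 0.003
  tr <- suppressWarnings(simulate_invitro(p_uM, m0 = m0, t_end = 8,
                                          N = 400))
  mo <- simulate_invitro_moments(p_uM, m0 = m0, t_end = 8)
  expect_lte(max(abs(mo$m + mo$M - m0)) / m0, 1e-6)
  M_sz <- approx(tr$time, tr$M, mo$time)$y
  expect_lte(max(abs(M_sz - mo$M)) / m0, 0.02)

  # elongation/secondary off: the source alone gives M = 2*k_n*t
  lin <- inert_params()
  lin$k_n <- p_uM$k_n
  mo2 <- simulate_invitro_moments(lin, m0 = 3, t_end = 10)
  expect_equal(mo2$M[-1], 2 * lin$k_n * mo2$time[-1], tolerance = 1e-5)
})

test_that("reference-scale saturation behavior holds at moment level", {
  # sigmoidal growth of toxic mass to the initial monomer pool within hours
  mo <- simulate_invitro_moments(p_uM, t_end = 2)
  n <- length(mo$time)
  expect_equal(mo$M[n], p_uM$m_0, tolerance = 0.01)
  tau <- halftime_numeric(mo)
  expect_gt(tau, 0.1); expect_lt(tau, 1)   # saturates within hours
  # sigmoid: growth fastest in the interior
  growth <- diff(mo$M)
  expect_gt(which.max(growth), 2)
})

test_that("linearization coefficients follow the closed forms", {
  m0 <- 1e-6
  co <- linearization_coefficients(p_M, m0)
  a_ref <- p_M$k_2 * m0^2 * p_M$K_m / (p_M$K_m + m0^2)
  expect_equal(co$a, a_ref)
  expect_equal(co$b - co$a, 2e4)           # 2 * m0 * k_plus
  expect_true(co$b >= co$a && co$a > 0)

  # saturation off: a -> k_2 * m0^2
  psat <- p_M; psat$K_m <- 1e12
  expect_equal(linearization_coefficients(psat, m0)$a,
               p_M$k_2 * m0^2, tolerance = 1e-10)
  co0 <- linearization_coefficients(p_M, 0)
  expect_equal(co0$a, 0); expect_equal(co0$b, 0)
})

test_that("linearized mass curve inverts exactly at the analytic halftime", {
  co <- linearization_coefficients(p_M)
  m0 <- p_M$m_0
  # value at the origin is a small non-positive offset
  expect_lte(abs(linearized_mass(0, p_M)), p_M$k_n / (2 * co$a))
  # asymptotic growth rate of log M equals a + sqrt(ab) (finite differences)
  t1 <- 1.5; h <- 1e-4
  slope <- (log(linearized_mass(t1 + h, p_M)) -
              log(linearized_mass(t1 - h, p_M))) / (2 * h)
  expect_equal(slope, co$a + sqrt(co$a * co$b), tolerance = 1e-4)
  # the halftime formula is the exact algebraic inversion
  expect_equal(linearized_mass(halftime_linear(p_M), p_M), m0 / 2,
               tolerance = 1e-10)
  degenerate <- p_M; degenerate$k_2 <- 0
  expect_error(linearized_mass(1, degenerate), "undefined")
})

test_that("analytic halftime matches its frozen value and the simulation", {
  # frozen direct evaluations at the reference concentration (hour units)
  expect_equal(halftime_linear(p_M, simplified = TRUE), 0.4000838,
               tolerance = 1e-6)
  expect_equal(halftime_linear(p_M), 0.3999540, tolerance = 1e-6)
  # full and simplified forms agree over the sweep range
  for (m0 in 10^seq(-7, -5, by = 0.5))
    expect_equal(halftime_linear(p_M, m0, simplified = TRUE),
                 halftime_linear(p_M, m0), tolerance = 0.05)
  # numerical halftime (moment integration is the oracle) within 25%
  for (m0M in c(1e-7, 1e-6, 1e-5)) {
    m0 <- m0M * 1e6
    mo <- simulate_invitro_moments(p_uM, m0 = m0, t_end = 40, n_out = 4001)
    tau_num <- halftime_numeric(mo, m0)
    expect_equal(halftime_linear(p_uM, m0), tau_num, tolerance = 0.25)
  }
  unseeded <- p_M; unseeded$k_n <- 0
  expect_error(halftime_linear(unseeded), "k_n")
})

test_that("halftime is most sensitive to elongation, least to nucleation", {
  base <- halftime_linear(p_M, 1e-6)
  spread <- function(field) {
    taus <- vapply(10^seq(-2, 2, by = 1), function(f) {
      q <- p_M; q[[field]] <- q[[field]] * f
      halftime_linear(q, 1e-6)
    }, numeric(1))
    diff(range(log(taus)))
  }
  s <- vapply(c("k_n", "k_2", "k_plus"), spread, numeric(1))
  expect_lt(s[["k_n"]], s[["k_2"]])
  expect_lt(s[["k_2"]], s[["k_plus"]])
  expect_gt(base, 0)
})

test_that("numerical halftime interpolates and signals non-crossing", {
  # synthetic monotone curve M = m0 * t / (1 + t) crosses m0/2 at t = 1
  fake <- structure(list(time = seq(0, 10, by = 0.01),
                         M = 5 * seq(0, 10, by = 0.01) /
                           (1 + seq(0, 10, by = 0.01)),
                         meta = list(params = list(m_0 = 5))),
                    class = "moment_trajectory")
  expect_equal(halftime_numeric(fake), 1, tolerance = 1e-3)
  short <- fake
  keep <- short$time < 0.5
  short$time <- short$time[keep]; short$M <- short$M[keep]
  expect_true(is.na(halftime_numeric(short)))
})

test_that("truncation refinement leaves the mass curve unchanged", {
  m0 <- 0.001
  a <- suppressWarnings(simulate_invitro(p_uM, m0 = m0, t_end = 6, N = 200))
  b <- suppressWarnings(simulate_invitro(p_uM, m0 = m0, t_end = 6, N = 400))
  expect_lte(max(abs(a$M - b$M)) / m0, 1e-3)
})
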