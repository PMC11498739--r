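# Rate-matrix structure and exact matrix-exponential propagation.

test_that("rate matrix has conservation structure and correct diagonals", {
  # all rates zero -> no fluxes at all
  p0 <- lct_params(f_abs_oral = 1, k_abs_inh = 0)
  A0 <- build_rate_matrix(p0, "CFMP")
  expect_equal(A0, matrix(0, 11, 11,
                          dimnames = list(lct_compartments(),
                                          lct_compartments())))

  # volunteer 2 oral CFMP values: diagonals equal minus total outflow
  p2 <- lct_params(f_abs_oral = 0.96, k_abs_oral = 2.3, k_BS = 0.06,
                   k_SB = 0.002, k_BM_CFMP = 0.03, k_BM_NO_CFMP = 0.03,
                   k_MU_CFMP = 0.40, k_MF_CFMP = 0.03)
  A <- build_rate_matrix(p2, "CFMP")
  expect_equal(A["B", "B"], -(0.06 + 0.03 + 0.03))
  expect_equal(A["GI", "GI"], -2.3)
  # sinks have no outflow
  expect_equal(unname(A[, "U"]), numeric(11))
  expect_equal(unname(A[, "F"]), numeric(11))
  expect_equal(unname(A[, "Mnm"]), numeric(11))

  # closed system: every column sums to zero, off-diagonals non-negative
  set.seed(101)
  for (i in 1:100) {
    p <- random_params()
    for (m in c("CFMP", "3PBA")) for (topo in c("parallel", "shared")) {
      A <- build_rate_matrix(p, m, topo)
      expect_lt(max(abs(colSums(A))), 1e-12)
      expect_true(all(A - diag(diag(A)) >= 0))
    }
  }

  expect_error(lct_params(k_BS = -1), "negative rate")
  expect_error(lct_params(f_abs_oral = 1.2), "fraction")
})

test_that("propagation matches closed-form asymptotic urinary fractions", {
  # empty schedule: identically zero
  p <- lct_params(f_abs_oral = 1, k_abs_oral = 2, k_BM_CFMP = 0.5,
                  k_BM_NO_CFMP = 0.5, k_MU_CFMP = 0.3)
  sim0 <- propagate(lct_schedule(horizon = 50), p, "CFMP", c(0, 10, 50))
  expect_equal(max(abs(sim0$states)), 0)

  # linear chain GI -> B -> M -> U, bolus 1000: U(inf) = 500 exactly
  # (f * k_BM/(k_BM+k_BM_NO) * k_MU/(k_MU+k_MF) = 1 * 0.5 * 1)
  sim <- propagate(schedule_bolus("oral", 1000, horizon = 2000), p,
                   "CFMP", c(100, 2000))
  expect_equal(unname(sim$states[2, "U"]), 500, tolerance = 1e-10)

  # volunteer 2 values: asymptotic fraction 0.96*0.5*(0.40/0.43)
  p2 <- lct_params(f_abs_oral = 0.96, k_abs_oral = 2.3, k_BS = 0.06,
                   k_SB = 0.002, k_BM_CFMP = 0.03, k_BM_NO_CFMP = 0.03,
                   k_MU_CFMP = 0.40, k_MF_CFMP = 0.03)
  sim2 <- propagate(schedule_bolus("oral", 1, horizon = 2e4), p2,
                    "CFMP", 2e4)
  expect_equal(unname(sim2$states[1, "U"]), 0.96 * 0.5 * 0.40 / 0.43,
               tolerance = 1e-6)
  expect_equal(unname(sim2$states[1, "U"]),
               asymptotic_urinary_fraction(p2, "CFMP"),
               tolerance = 1e-6)

  # storage exchange returns all mass: fraction unchanged by k_BS/k_SB,
  # verified numerically at 2000 h within 0.1%
  set.seed(7)
  for (i in 1:5) {
    p <- random_params()
    sim <- propagate(schedule_bolus("oral", 1, horizon = 2e4), p,
                     "CFMP", 2e4)
    expect_equal(unname(sim$states[1, "U"]),
                 asymptotic_urinary_fraction(p, "CFMP"),
                 tolerance = 1e-3)
  }
})

test_that("mass balance, non-negativity and monotone sinks hold on random schedules", {
  set.seed(11)
  for (i in 1:10) {
    p <- random_params()
    sched <- lct_schedule(
      lct_event("oral", 0, stats::runif(1, 10, 1000)),
      lct_event("dermal", stats::runif(1, 0, 5),
                stats::runif(1, 10, 1000), surface_removal = 8),
      lct_event("inhalation", 2, stats::runif(1, 1, 100),
                duration = 3),
      lct_event("systemic", 10, stats::runif(1, 1, 100)),
      horizon = 72)
    sim <- propagate(sched, p, "CFMP", seq(0, 72, by = 1.5))
    balance <- rowSums(sim$states) + sim$removed_cum - sim$input_cum
    expect_lt(max(abs(balance)) / max(sim$input_cum), 1e-8)
    expect_true(all(sim$states > -1e-9))
    expect_true(all(diff(sim$states[, "U"]) > -1e-9))
    expect_true(all(diff(sim$states[, "F"]) > -1e-9))
    expect_equal(unname(sim$QU),
                 unname(sim$states[, "M"] * p[["k_MU_CFMP"]]))
  }
})

test_that("doubling every event amount doubles every output exactly", {
  set.seed(13)
  p <- random_params()
  ev1 <- lct_schedule(lct_event("oral", 0, 100),
                      lct_event("dermal", 1, 50, surface_removal = 7),
                      horizon = 48)
  ev2 <- lct_schedule(lct_event("oral", 0, 200),
                      lct_event("dermal", 1, 100, surface_removal = 7),
                      horizon = 48)
  s1 <- propagate(ev1, p, "CFMP", seq(0, 48, 2))
  s2 <- propagate(ev2, p, "CFMP", seq(0, 48, 2))
  expect_identical(2 * s1$states, s2$states)
})

test_that("matrix-exponential solution agrees with a stiff ODE integrator", {
  set.seed(17)
  worst <- 0
  for (i in 1:50) {
    p <- random_params()
    route <- sample(c("oral", "dermal", "systemic"), 1)
    times <- c(0.5, 1, 2, 6, 12, 24, 48)
    sim <- propagate(schedule_bolus(route, 1000, horizon = 48), p,
                     "CFMP", times)
    ref <- ode_oracle(p, route, 1000, times)
    scale <- pmax(abs(ref), 1e-6 * max(abs(ref)))
    worst <- max(worst, max(abs(sim$states - ref) / scale))
  }
  expect_lt(worst, 1e-6)
})

test_that("impulse-response matrix reproduces direct simulation by superposition", {
  p2 <- lct_params(f_abs_oral = 0.96, k_abs_oral = 2.3, k_BS = 0.06,
                   k_SB = 0.002, k_BM_CFMP = 0.03, k_BM_NO_CFMP = 0.03,
                   k_MU_CFMP = 0.40, k_MF_CFMP = 0.03)

  # single bin, interval covering effectively [0, inf): the asymptotic
  # urinary fraction
  G <- impulse_response_matrix(p2, "oral", 0, cbind(0, 2e4))
  expect_equal(G[1, 1], asymptotic_urinary_fraction(p2, "CFMP"),
               tolerance = 1e-6)

  # causality: a dose bin after the last collection gives a zero column
  G2 <- impulse_response_matrix(p2, "oral", c(0, 60), cbind(0, 48))
  expect_equal(G2[1, 2], 0)

  # superposition vs direct double-bolus simulation
  set.seed(19)
  for (i in 1:5) {
    p <- random_params()
    iv <- cbind(c(0, 12, 24), c(12, 24, 48))
    G <- impulse_response_matrix(p, "oral", c(0, 5), iv)
    expect_true(all(G >= 0))
    amts <- stats::runif(2, 10, 1000)
    direct <- urine_intervals(
      p, lct_schedule(lct_event("oral", 0, amts[1]),
                      lct_event("oral", 5, amts[2]), horizon = 48), iv)
    expect_equal(drop(G %*% amts), unname(direct), tolerance = 1e-8)
  }

  expect_error(
    impulse_response_matrix(p2, "oral", 0, cbind(c(0, 5), c(12, 24))),
    "overlapping")
})
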