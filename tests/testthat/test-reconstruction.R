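# Monte-Carlo reverse dosimetry and exceedance probabilities.

test_that("parameter sampling honours the lognormal summaries", {
  ens <- fixture_ensembles("table2")

  # zero spread returns the means exactly
  deg <- degenerate_ensemble(fixture_params(3, dermal = FALSE))
  p <- sample_parameters(list(deg), seed = 1)
  expect_equal(unclass(p)[deg$free], deg$summary$mean)

  # moment recovery: the sample mean of k_MU_CFMP matches the printed
  # mean for volunteer 1 (0.29) within 1%
  set.seed(42)
  v1 <- ens[["1"]]
  draws <- replicate(1e5, NA_real_)
  mu <- v1$lognormal$mu[["k_MU_CFMP"]]
  sig <- v1$lognormal$sigma[["k_MU_CFMP"]]
  draws <- vapply(seq_len(1e5), function(i)
    sample_parameters(list(v1))[["k_MU_CFMP"]], 0)
  expect_equal(mean(draws), 0.29, tolerance = 0.01)

  # empirical law matches the analytic lognormal (KS distance < 0.01)
  ks <- suppressWarnings(stats::ks.test(draws, stats::plnorm, mu, sig))
  expect_lt(unname(ks$statistic), 0.01)

  # deterministic given seed
  p1 <- sample_parameters(ens, seed = 99)
  p2 <- sample_parameters(ens, seed = 99)
  expect_identical(p1, p2)
})

test_that("reconstruction recovers a known synthetic daily dose", {
  mk <- make_applicator_study()
  rec <- reconstruct(mk$study$series, mk$scenario,
                     fixture_ensembles("table2"), n_accept = 100,
                     seed = 5)
  expect_true(rec$quantifiable)
  expect_equal(nrow(rec$doses), 100)
  expect_true(all(rec$R <= 0.05))
  med <- apply(rec$daily_pmol, 2, stats::median)
  expect_equal(unname(med), rep(1400, 3), tolerance = 0.15)

  # stored R round-trips through a fresh forward simulation
  ur <- mk$study$series$data
  iv <- cbind(ur$t_start_h, ur$t_end_h)
  keep <- !ur$censored
  for (i in c(1, 50, 100)) {
    p <- lct_params(.values = rec$params[i, ])
    G <- impulse_response_matrix(p, "oral", rec$bins, iv)
    pred <- drop(G %*% rec$doses[i, ])
    R <- mean(abs(pred[keep] - ur$value_pmol_per_kg[keep]) /
                ur$value_pmol_per_kg[keep])
    expect_equal(R, rec$R[i], tolerance = 1e-9)
  }

  # daily sums equal bin sums over each 24-h window
  win <- findInterval(rec$bins, rec$windows, rightmost.closed = TRUE)
  for (w in 1:3)
    expect_equal(rec$daily_pmol[, w],
                 rowSums(rec$doses[, win == w, drop = FALSE]))
})

test_that("reconstruction is linear in the observations", {
  mk <- make_applicator_study(cv = 0.05, seed = 31)
  s1 <- mk$study$series
  d2 <- s1$data
  d2$value_pmol_per_kg <- 2 * d2$value_pmol_per_kg
  s2 <- lct_series(d2, s1$schedule, s1$subject)
  ens <- fixture_ensembles("table2")
  r1 <- reconstruct(s1, mk$scenario, ens, n_accept = 25, seed = 8)
  r2 <- reconstruct(s2, mk$scenario, ens, n_accept = 25, seed = 8)
  expect_equal(r2$doses, 2 * r1$doses, tolerance = 1e-8)
})

test_that("a fully censored series yields a zero, non-quantifiable ensemble", {
  scen <- scenario_hourly("oral", c(8, 9, 10))
  ws <- generate_worker_study(c(0, 0, 0), scen, design_applicator(1),
                              fixture_params(2, dermal = FALSE),
                              noise = lct_noise(loq_urine = 5, seed = 2))
  expect_true(all(ws$series$data$censored))
  rec <- reconstruct(ws$series, scen, fixture_ensembles("table2"),
                     n_accept = 50, seed = 3)
  expect_false(rec$quantifiable)
  expect_equal(max(rec$doses), 0)
  expect_equal(max(rec$daily_pmol), 0)
})

test_that("exceedance probabilities behave as counting fractions", {
  # constructed ensemble: exactly half the draws above the threshold
  rec <- structure(list(
    doses = matrix(0, 10, 1),
    daily_pmol = matrix(c(rep(1000, 5), rep(2000, 5)), ncol = 1),
    R = rep(0, 10), params = NULL, bins = 8, route = "oral",
    windows = c(0, 24), quantifiable = TRUE, attempts = 10L, seed = 1),
    class = "lct_recon")
  rep1 <- exceedance(rec, threshold = 1400, n_boot = 200)
  expect_equal(rep1$p_exceed_pct, 50)
  expect_true(rep1$ci_low_pmol <= rep1$median_pmol &&
                rep1$median_pmol <= rep1$ci_high_pmol)

  # all below -> 0%
  expect_equal(exceedance(rec, threshold = 5000,
                          n_boot = 200)$p_exceed_pct, 0)

  # monotone: lowering the threshold never lowers the probability
  probs <- vapply(c(3000, 2000, 1500, 1200, 800, 100), function(th)
    exceedance(rec, threshold = th, n_boot = 10)$p_exceed_pct, 0)
  expect_true(all(diff(probs) >= 0))
  expect_true(all(probs >= 0 & probs <= 100))
})

test_that("exceedance probabilities are stable in the ensemble size", {
  mk <- make_applicator_study(seed = 77)
  ens <- fixture_ensembles("table2")
  r1 <- reconstruct(mk$study$series, mk$scenario, ens,
                    n_accept = 150, seed = 4)
  r2 <- reconstruct(mk$study$series, mk$scenario, ens,
                    n_accept = 300, seed = 104)
  p1 <- exceedance(r1, n_boot = 100)$p_exceed_pct
  p2 <- exceedance(r2, n_boot = 100)$p_exceed_pct
  expect_lt(max(abs(p1 - p2)), 8)
})

test_that("dose-recovery bias stays below 15% median across seeds", {
  ens <- fixture_ensembles("table2")
  rel_err <- vapply(1:5, function(s) {
    mk <- make_applicator_study(seed = 200 + s)
    rec <- reconstruct(mk$study$series, mk$scenario, ens,
                       n_accept = 60, seed = 300 + s)
    med <- apply(rec$daily_pmol, 2, stats::median)
    stats::median(abs(med - 1400) / 1400)
  }, 0)
  expect_lt(stats::median(rel_err), 0.15)
})
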