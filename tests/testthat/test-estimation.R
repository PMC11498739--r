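# Fit-error metric and multi-start ensemble estimation.

make_series <- function(obs, pred_equal = FALSE) {
  lct_series(data.frame(
    matrix = "urine", analyte = "CFMP",
    t_start_h = seq_along(obs) - 1, t_end_h = seq_along(obs),
    value_pmol_per_kg = obs, censored = FALSE),
    schedule_bolus("oral", 1, horizon = length(obs)))
}

test_that("fit error is the mean absolute relative deviation with LOQ rules", {
  s <- make_series(c(10, 20, 30, 40, 50))
  expect_equal(fit_error(c(10, 20, 30, 40, 50), s), 0)
  expect_equal(fit_error(1.2 * c(10, 20, 30, 40, 50), s), 0.2)
  # mixed over/under-prediction: hand-computed mean of |delta|/obs
  pred <- c(12, 15, 33, 40, 45)
  expect_equal(fit_error(pred, s),
               (2 / 10 + 5 / 20 + 3 / 30 + 0 + 5 / 50) / 5)

  # censored rows: zero when predicted at/below LOQ, (pred-LOQ)/LOQ above
  d <- s$data
  d$censored <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  d$value_pmol_per_kg[4:5] <- 5  # LOQ
  sc <- lct_series(d, s$schedule)
  expect_equal(fit_error(c(10, 20, 30, 4, 10), sc),
               (0 + 0 + 0 + 0 + (10 - 5) / 5) / 5)

  d$censored <- rep(TRUE, 5)
  expect_error(fit_error(rep(1, 5), lct_series(d, s$schedule)),
               "all observations censored")
})

test_that("noiseless multi-start fitting recovers the identifiable parameters", {
  truth <- fixture_params(1, dermal = FALSE)
  st <- generate_volunteer_study(truth, design_volunteer_oral(),
                                 noise = lct_noise(0, 0, seed = 3))
  free <- setdiff(lct_stage_params("oral"), "f_abs_oral")
  ranges <- stats::setNames(rep(list(c(0.005, 5)), length(free)), free)
  ens <- fit_ensemble(st$series, free,
                      fixed = lct_params(f_abs_oral = truth[["f_abs_oral"]]),
                      ranges = ranges, n_sets = 15, seed = 1)

  # draw-count exactness and round-trip acceptance
  expect_equal(nrow(ens$draws), 15)
  expect_equal(length(ens$errors), 15)
  expect_true(all(ens$errors <= 0.20))
  for (i in c(1, 8, 15)) {
    p <- ens$fixed
    p[ens$free] <- ens$draws[i, ]
    expect_equal(fit_error(predict_series(validate_lct_params(p),
                                          st$series), st$series),
                 ens$errors[i], tolerance = 1e-9)
  }

  # noiseless global optimum is reachable
  expect_lt(min(ens$errors), 1e-4)

  # identifiable parameters (urinary transfer, storage return, branch
  # fraction) recovered within 5% by the ensemble median; absorption
  # and blood-side rates individually sit on a flip-flop ridge and are
  # only identified through the branch fraction
  med <- apply(ens$draws, 2, stats::median)
  for (nm in c("k_MU_CFMP", "k_MU_3PBA", "k_SB"))
    expect_equal(unname(med[nm]), unname(unclass(truth)[nm]),
                 tolerance = 0.05)
  bf <- function(v) v["k_BM_CFMP"] / (v["k_BM_CFMP"] + v["k_BM_NO_CFMP"])
  expect_equal(unname(bf(med)), unname(bf(unclass(truth))),
               tolerance = 0.05)

  # summary is recomputable from the draws
  expect_equal(ens$summary$mean, colMeans(ens$draws), tolerance = 1e-12)
  expect_equal(ens$summary$sd, apply(ens$draws, 2, stats::sd),
               tolerance = 1e-12)
  expect_equal(ens$lognormal$mu, apply(ens$draws, 2, function(v)
    mean(log(v))), tolerance = 1e-12)
})

test_that("fitting is deterministic under a fixed seed", {
  truth <- fixture_params(2, dermal = FALSE)
  st <- generate_volunteer_study(truth, design_volunteer_oral(),
                                 noise = lct_noise(0.05, 0.05, seed = 5),
                                 analytes = "CFMP")
  free <- c("k_BM_CFMP", "k_BM_NO_CFMP", "k_MU_CFMP", "k_MF_CFMP")
  ranges <- stats::setNames(rep(list(c(0.005, 5)), 4), free)
  fixed <- truth
  e1 <- fit_ensemble(st$series, free, fixed, ranges, n_sets = 3, seed = 42)
  e2 <- fit_ensemble(st$series, free, fixed, ranges, n_sets = 3, seed = 42)
  expect_identical(e1$draws, e2$draws)
  expect_identical(e1$errors, e2$errors)
})

test_that("an impossible error cap reports convergence failure", {
  truth <- fixture_params(2, dermal = FALSE)
  st <- generate_volunteer_study(truth, design_volunteer_oral(),
                                 noise = lct_noise(0.2, 0.2, seed = 6),
                                 analytes = "CFMP")
  free <- c("k_BM_CFMP", "k_MU_CFMP")
  ranges <- stats::setNames(rep(list(c(0.005, 5)), 2), free)
  expect_error(
    fit_ensemble(st$series, free, truth, ranges, n_sets = 1,
                 error_cap = 0, seed = 2, attempt_budget = 5),
    "convergence failure.*best error")
})

test_that("dermal second stage recovers skin-penetration rates with oral values fixed", {
  truth <- fixture_params(2)  # includes k_DinB = 0.49
  st <- generate_volunteer_study(truth, design_volunteer_dermal(),
                                 dose_pmol_kg = 0.56e6,
                                 noise = lct_noise(0, 0, seed = 4),
                                 subject = "V2")
  oral_ens <- degenerate_ensemble(truth)
  free <- c("k_DDin", "k_DinB", "k_DinMD_CFMP", "k_DinMD_3PBA")
  ens <- fit_dermal_stage(st$series, oral_ens, free = free,
                          ranges = stats::setNames(
                            rep(list(c(1e-4, 5)), 4), free),
                          n_sets = 6, seed = 9)
  med <- apply(ens$draws, 2, stats::median)
  expect_equal(unname(med["k_DinB"]), 0.49, tolerance = 0.10)
  expect_equal(unname(med["k_DDin"]), 0.0005, tolerance = 0.10)
  expect_lt(min(ens$errors), 1e-4)
})

test_that("a zero-dose dermal study is flagged unidentifiable", {
  truth <- fixture_params(2)
  st <- generate_volunteer_study(truth, design_volunteer_dermal(),
                                 dose_pmol_kg = 0,
                                 noise = lct_noise(0, 0, seed = 4))
  expect_error(
    fit_dermal_stage(st$series, degenerate_ensemble(truth), n_sets = 2),
    "unidentifiable")
})

test_that("flat fit-error profiles raise a weak-identifiability warning", {
  truth <- fixture_params(2)
  st <- generate_volunteer_study(truth, design_volunteer_oral(),
                                 noise = lct_noise(0, 0, seed = 4))
  # k_DDin plays no role in an oral study: profile is exactly flat
  expect_warning(
    prof <- profile_identifiability(st$series, "k_DDin",
                                    truth, lower = 1e-3, upper = 1e-2),
    "weakly identifiable")
  expect_lt(max(prof$error) - min(prof$error), 1e-12)
  # a strongly identifiable parameter does not warn
  expect_no_warning(
    profile_identifiability(st$series, "k_MU_CFMP", truth,
                            lower = 0.4 / sqrt(10), upper = 0.4 * sqrt(10)))
})
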