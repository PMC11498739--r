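# Synthetic volunteer and worker study generators.

test_that("zero noise and zero LOQ reproduce the simulation exactly", {
  truth <- fixture_params(2, dermal = FALSE)
  st <- generate_volunteer_study(truth, design_volunteer_oral(),
                                 noise = lct_noise(0, 0, seed = 1))
  pred <- predict_series(truth, st$series)
  expect_equal(pred, st$series$data$value_pmol_per_kg, tolerance = 1e-12)
  expect_false(any(st$series$data$censored))
})

test_that("multiplicative noise has the requested coefficient of variation", {
  truth <- fixture_params(2, dermal = FALSE)
  # 100 replicate studies; empirical CV of one blood and one urine
  # observation within [0.07, 0.13] for a nominal CV of 0.1
  vals <- vapply(1:100, function(s) {
    st <- generate_volunteer_study(truth, design_volunteer_oral(),
                                   noise = lct_noise(0.1, 0.1, seed = s),
                                   analytes = "CFMP")
    d <- st$series$data
    c(d$value_pmol_per_kg[d$matrix == "blood"][5],
      d$value_pmol_per_kg[d$matrix == "urine"][5])
  }, numeric(2))
  cv_blood <- stats::sd(vals[1, ]) / mean(vals[1, ])
  cv_urine <- stats::sd(vals[2, ]) / mean(vals[2, ])
  expect_gt(cv_blood, 0.07); expect_lt(cv_blood, 0.13)
  expect_gt(cv_urine, 0.07); expect_lt(cv_urine, 0.13)
})

test_that("dermal exposure peaks later than oral for the same volunteer", {
  oral <- fixture_params(3, dermal = FALSE)
  derm <- fixture_params(3)
  sched_o <- schedule_bolus("oral", 1000, horizon = 84)
  sched_d <- schedule_bolus("dermal", 1000, horizon = 84,
                            surface_removal = 6)
  tt <- seq(0.5, 84, by = 0.5)
  qu_o <- propagate(sched_o, oral, "CFMP", tt)$QU
  qu_d <- propagate(sched_d, derm, "CFMP", tt)$QU
  expect_lt(tt[which.max(qu_o)], tt[which.max(qu_d)])
})

test_that("worker generator respects linearity and censoring", {
  truth <- fixture_params(6, dermal = FALSE)
  scen <- scenario_hourly("oral", c(8, 10, 12))
  iv <- design_applicator(1)

  # all-zero doses -> fully censored series (any positive LOQ)
  ws0 <- generate_worker_study(c(0, 0, 0), scen, iv, truth,
                               noise = lct_noise(loq_urine = 0.01,
                                                 seed = 3))
  expect_true(all(ws0$series$data$censored))

  # doubling doses doubles every non-censored observation (zero noise)
  ws1 <- generate_worker_study(c(100, 200, 300), scen, iv, truth,
                               noise = lct_noise(0, 0, seed = 3))
  ws2 <- generate_worker_study(c(200, 400, 600), scen, iv, truth,
                               noise = lct_noise(0, 0, seed = 3))
  expect_equal(ws2$series$data$value_pmol_per_kg,
               2 * ws1$series$data$value_pmol_per_kg, tolerance = 1e-12)

  # truth record daily sums match the bin structure
  expect_equal(sum(ws1$truth$daily_pmol), 600)
})

test_that("identical seeds give identical synthetic datasets", {
  truth <- fixture_params(1, dermal = FALSE)
  a <- generate_volunteer_study(truth, design_volunteer_oral(),
                                noise = lct_noise(0.2, 0.15, 5, 2,
                                                  seed = 11))
  b <- generate_volunteer_study(truth, design_volunteer_oral(),
                                noise = lct_noise(0.2, 0.15, 5, 2,
                                                  seed = 11))
  expect_identical(a$series$data, b$series$data)
})

test_that("truth records and series round-trip through files", {
  truth <- fixture_params(6, dermal = FALSE)
  scen <- scenario_hourly("oral", c(8, 10))
  ws <- generate_worker_study(c(50, 70), scen, design_applicator(1),
                              truth, noise = lct_noise(0.1, seed = 2))
  tmp <- withr::local_tempdir()
  jp <- file.path(tmp, "truth.json")
  write_truth_json(ws$truth, jp)
  back <- read_truth_json(jp)
  expect_equal(unclass(back$params), unclass(ws$truth$params),
               tolerance = 1e-12)
  expect_equal(back$doses_pmol, ws$truth$doses_pmol)

  sp <- file.path(tmp, "series.csv")
  write_series_csv(ws$series, sp)
  back_s <- read_series_csv(sp, ws$series$schedule)
  expect_equal(back_s$data$value_pmol_per_kg,
               ws$series$data$value_pmol_per_kg, tolerance = 1e-12)
  expect_identical(back_s$data$censored, ws$series$data$censored)
})
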