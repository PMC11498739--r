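# Shared helpers: random parameter draws, an independent stiff ODE
# oracle (deSolve::lsoda on the same rate matrix), and a degenerate
# single-draw ensemble wrapper.

random_params <- function() {
  rates <- exp(stats::runif(length(cyhalotk:::.lct_rate_names),
                            log(1e-3), log(2)))
  names(rates) <- cyhalotk:::.lct_rate_names
  lct_params(.values = c(rates,
                         f_abs_oral = stats::runif(1, 0.2, 1),
                         f_abs_dermal = 1, f_abs_inh = 1))
}

# independent propagation of a single bolus with a stiff integrator
ode_oracle <- function(params, route, dose, times, moiety = "CFMP") {
  A <- build_rate_matrix(params, moiety)
  x0 <- stats::setNames(numeric(11), lct_compartments())
  en <- cyhalotk:::route_entry(route, params)
  x0[en$comp] <- en$f * dose
  out <- deSolve::lsoda(
    y = x0, times = sort(unique(c(0, times))),
    func = function(t, y, parms) list(drop(parms %*% y)), parms = A,
    rtol = 1e-11, atol = 1e-12)
  out[match(round(times, 10), round(out[, "time"], 10)), -1, drop = FALSE]
}

degenerate_ensemble <- function(params, free = lct_stage_params("oral"),
                                subject = "truth") {
  v <- unclass(params)[free]
  structure(list(
    draws = matrix(v, 1, dimnames = list(NULL, free)),
    errors = 0, free = free, fixed = params,
    summary = list(mean = v, sd = 0 * v),
    lognormal = list(mu = log(pmax(v, 1e-300)), sigma = 0 * v),
    provenance = list(subject = subject, stage = "degenerate", seed = NA)
  ), class = "lct_ensemble")
}

# applicator-style synthetic study used by several tests: 3 work days,
# hourly oral exposure 08:00-15:00, serial voids
make_applicator_study <- function(truth = fixture_params(6, dermal = FALSE),
                                  daily_pmol = 1400, n_days = 3,
                                  cv = 0.1, loq = 1, seed = 21) {
  work_hours <- as.numeric(outer(8:15, 24 * (seq_len(n_days) - 1), "+"))
  scen <- scenario_hourly("oral", work_hours)
  doses <- rep(daily_pmol / 8, length(work_hours))
  ws <- generate_worker_study(doses, scen, design_applicator(n_days),
                              truth,
                              noise = lct_noise(cv_urine = cv,
                                                loq_urine = loq,
                                                seed = seed))
  list(study = ws, scenario = scen)
}
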