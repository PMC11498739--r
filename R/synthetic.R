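# Synthetic-data generator: volunteer-style controlled-dosing studies
# and worker-style biomonitoring series with known ground truth, so the
# fitting and reconstruction stages are testable end to end without the
# (unpublished) original datasets.

#' Assay-noise model
#'
#' Multiplicative lognormal noise, independent across observations,
#' with below-LOQ censoring; positive-valued assay data make the
#' lognormal the natural error family. `cv = 0` reproduces the
#' simulation exactly; `loq = 0` disables censoring.
#'
#' @param cv_blood,cv_urine coefficient of variation per matrix
#' @param loq_blood,loq_urine limits of quantification, pmol/kg bw
#'   (blood) and pmol/kg bw per collection (urine)
#' @param seed integer seed used by the generators
#' @return list of class `lct_noise`
#' @export
lct_noise <- function(cv_blood = 0.1, cv_urine = 0.1,
                      loq_blood = 0, loq_urine = 0, seed = 1) {
  stopifnot(cv_blood >= 0, cv_urine >= 0, loq_blood >= 0, loq_urine >= 0)
  structure(list(cv_blood = cv_blood, cv_urine = cv_urine,
                 loq_blood = loq_blood, loq_urine = loq_urine,
                 seed = seed), class = "lct_noise")
}

mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sigma^2 / 2, sigma)  # mean-1 multiplicative factor
}

#' Volunteer study designs
#'
#' `design_volunteer_oral()`: a single oral bolus at time zero with
#' blood sampling and serial urine collections over ~84 h.
#' `design_volunteer_dermal()`: a 6-h skin deposit (applied at time
#' zero, washed off at 6 h) with the same sampling scheme.
#'
#' @param blood_times blood sampling times (h)
#' @param urine_breaks urine collection boundaries (h)
#' @return list of class `lct_design`
#' @export
design_volunteer_oral <- function(
    blood_times = c(1, 2, 3, 4, 6, 8, 12, 24, 30, 36, 48, 60, 72, 84),
    urine_breaks = c(0, 3, 6, 9, 12, 24, 30, 36, 48, 60, 72, 84)) {
  structure(list(kind = "volunteer-oral", route = "oral",
                 exposure_duration = 0, surface_removal = NA_real_,
                 blood_times = blood_times, urine_breaks = urine_breaks),
            class = "lct_design")
}

#' @rdname design_volunteer_oral
#' @param exposure_duration hours the deposit stays on the skin
#' @export
design_volunteer_dermal <- function(
    blood_times = c(1, 2, 3, 4, 6, 8, 12, 24, 30, 36, 48, 60, 72, 84),
    urine_breaks = c(0, 3, 6, 9, 12, 24, 30, 36, 48, 60, 72, 84),
    exposure_duration = 6) {
  structure(list(kind = "volunteer-dermal", route = "dermal",
                 exposure_duration = 0,
                 surface_removal = exposure_duration,
                 blood_times = blood_times, urine_breaks = urine_breaks),
            class = "lct_design")
}

#' Default synthetic oral dose
#'
#' 0.025 mg/kg bw of LCT in molar units (~55,580 pmol/kg bw); any
#' positive value works because the model is linear in dose.
#'
#' @return pmol/kg bw
#' @export
default_oral_dose_pmol <- function() lct_ng_to_pmol(0.025e6)

#' Generate a synthetic volunteer study
#'
#' Forward-simulates both metabolites under the design's exposure,
#' samples the blood burden at the design's times and the urinary
#' amounts over its collection intervals, applies multiplicative
#' noise, and censors observations below the LOQ (the stored value of
#' a censored row is the LOQ). The returned truth record holds the
#' generating parameters, dose and schedule.
#'
#' @param params generating [lct_params()]
#' @param design [design_volunteer_oral()] / [design_volunteer_dermal()]
#' @param dose_pmol_kg administered dose, pmol/kg bw
#' @param noise [lct_noise()]
#' @param analytes which metabolites to observe
#' @param subject subject label
#' @param topology see [build_rate_matrix()]
#' @return list with `series` ([lct_series()]) and `truth`
#' @export
generate_volunteer_study <- function(params, design,
                                     dose_pmol_kg = default_oral_dose_pmol(),
                                     noise = lct_noise(),
                                     analytes = c("CFMP", "3PBA"),
                                     subject = "V1",
                                     topology = c("parallel", "shared")) {
  topology <- match.arg(topology)
  stopifnot(inherits(design, "lct_design"), dose_pmol_kg >= 0)
  sched <- schedule_bolus(design$route, dose_pmol_kg,
                          horizon = max(design$blood_times,
                                        design$urine_breaks),
                          surface_removal = design$surface_removal)
  iv <- cbind(design$urine_breaks[-length(design$urine_breaks)],
              design$urine_breaks[-1])
  set.seed(noise$seed)
  rows <- list()
  for (an in analytes) {
    blood <- blood_metabolite(params, sched, design$blood_times, an,
                              topology)
    urine <- urine_intervals(params, sched, iv, an, topology)
    blood_obs <- blood * mult_noise(length(blood), noise$cv_blood)
    urine_obs <- urine * mult_noise(length(urine), noise$cv_urine)
    bcens <- blood_obs < noise$loq_blood
    ucens <- urine_obs < noise$loq_urine
    rows[[length(rows) + 1]] <- data.frame(
      matrix = "blood", analyte = an,
      t_start_h = design$blood_times, t_end_h = design$blood_times,
      value_pmol_per_kg = ifelse(bcens, noise$loq_blood, blood_obs),
      censored = bcens)
    rows[[length(rows) + 1]] <- data.frame(
      matrix = "urine", analyte = an,
      t_start_h = iv[, 1], t_end_h = iv[, 2],
      value_pmol_per_kg = ifelse(ucens, noise$loq_urine, urine_obs),
      censored = ucens)
  }
  list(series = lct_series(do.call(rbind, rows), sched, subject),
       truth = list(params = params, dose_pmol_kg = dose_pmol_kg,
                    design = design, schedule = sched,
                    topology = topology))
}

#' Worker collection designs
#'
#' `design_applicator()`: serial voids over up to six days — within-day
#' voids every three hours from 08:00 to 20:00 plus a next-morning
#' void, time origin at midnight of the first monitored day.
#' `design_fieldworker()`: consecutive 24-h collections over 3-4 days.
#'
#' @param n_days monitored days
#' @return two-column matrix of urine-collection intervals (h)
#' @export
design_applicator <- function(n_days = 3) {
  stopifnot(n_days >= 1, n_days <= 6)
  voids <- sort(unique(as.numeric(
    outer(c(8, 11, 14, 17, 20), 24 * (seq_len(n_days) - 1), "+"))))
  voids <- c(voids, 24 * n_days)
  cbind(c(0, voids[-length(voids)]), voids)
}

#' @rdname design_applicator
#' @export
design_fieldworker <- function(n_days = 4) {
  stopifnot(n_days >= 3, n_days <= 4)
  cbind(24 * (seq_len(n_days) - 1), 24 * seq_len(n_days))
}

#' Generate a synthetic worker biomonitoring series
#'
#' Forward-simulates urinary CFMP over the worker's collection
#' intervals for a known dose profile on the scenario's bins, applies
#' multiplicative noise and LOQ censoring, and returns the observed
#' series with its truth record.
#'
#' @param true_doses_pmol dose per scenario bin, pmol/kg bw
#' @param scenario [scenario_hourly()] / [scenario_daily5()]
#' @param intervals collection intervals, e.g. [design_applicator()]
#' @param params generating [lct_params()]
#' @param noise [lct_noise()]
#' @param subject subject label
#' @param topology see [build_rate_matrix()]
#' @return list with `series` and `truth` (params, doses, daily sums)
#' @export
generate_worker_study <- function(true_doses_pmol, scenario, intervals,
                                  params, noise = lct_noise(),
                                  subject = "W1",
                                  topology = c("parallel", "shared")) {
  topology <- match.arg(topology)
  stopifnot(inherits(scenario, "lct_scenario"),
            all(true_doses_pmol >= 0),
            length(true_doses_pmol) == length(scenario$bin_times))
  intervals <- as.matrix(intervals)
  horizon <- max(intervals, scenario$bin_times)
  active <- true_doses_pmol > 0
  sched <- if (any(active)) {
    ev <- do.call(rbind, lapply(which(active), function(j)
      lct_event(scenario$route, scenario$bin_times[j],
                true_doses_pmol[j])))
    lct_schedule(ev, horizon = horizon)
  } else lct_schedule(horizon = horizon)
  urine <- urine_intervals(params, sched, intervals, "CFMP", topology)
  set.seed(noise$seed)
  obs <- urine * mult_noise(length(urine), noise$cv_urine)
  cens <- obs < noise$loq_urine
  data <- data.frame(matrix = "urine", analyte = "CFMP",
                     t_start_h = intervals[, 1], t_end_h = intervals[, 2],
                     value_pmol_per_kg = ifelse(cens, noise$loq_urine, obs),
                     censored = cens)
  windows <- seq(0, ceiling(horizon / 24) * 24, by = 24)
  win_id <- findInterval(scenario$bin_times, windows,
                         rightmost.closed = TRUE)
  daily <- vapply(seq_len(length(windows) - 1), function(w)
    sum(true_doses_pmol[win_id == w]), 0)
  list(series = lct_series(data, sched, subject),
       truth = list(params = params, doses_pmol = true_doses_pmol,
                    bin_times = scenario$bin_times, route = scenario$route,
                    daily_pmol = daily, windows = windows,
                    topology = topology))
}

#' Write / read a truth record as JSON
#'
#' @param truth truth record from a generator
#' @param path JSON path
#' @export
write_truth_json <- function(truth, path) {
  tr <- truth
  tr$params <- as.list(unclass(tr$params))
  tr$design <- NULL
  tr$schedule <- NULL
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$params <- lct_params(.values = unlist(j$params))
  j
}
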