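# Compartmental model core.
#
# Eleven states per metabolite sub-model, in fixed order:
#   D    LCT on the skin surface
#   Din  LCT inside skin structures
#   GI   LCT in the gastrointestinal lumen
#   RT   LCT in the respiratory tract
#   B    LCT in blood + tissues in fast equilibrium with blood
#   S    LCT stored in tissues (lipids / protein binding)
#   M    body burden of the metabolite (CFMP or 3-PBA)
#   MD   metabolite formed within the skin structures
#   Mnm  non-monitored metabolites (sink)
#   U    cumulative urinary metabolite (sink)
#   F    cumulative fecal metabolite (sink)
#
# The system is linear with constant coefficients, so each segment with
# piecewise-constant input is solved exactly with a matrix exponential.

.lct_compartments <- c("D", "Din", "GI", "RT", "B", "S",
                       "M", "MD", "Mnm", "U", "F")

#' Compartment names of the model state vector
#' @return character vector of length 11, in solver order
#' @export
lct_compartments <- function() .lct_compartments

#' Build the transfer-rate matrix of one metabolite sub-model
#'
#' Returns the matrix `A` of the linear system `dx/dt = A x + g(t)` over
#' the compartment order of [lct_compartments()]. Off-diagonal entry
#' `A[i, j]` is the first-order rate from compartment j into i; each
#' diagonal entry is minus the total outflow of its compartment, so all
#' column sums are zero (mass is conserved up to the explicit sinks).
#'
#' Under the default `"parallel"` topology the two metabolites are
#' independent sub-models sharing the LCT-side rates, and blood in the
#' CFMP sub-model drains only through the CFMP biotransformation rates
#' (one molecule of LCT yields one acid-side and one alcohol-side
#' moiety). The `"shared"` alternative drains blood (and internal skin)
#' through both metabolites' biotransformation rates, routing the other
#' metabolite's flux to the non-monitored sink.
#'
#' @param params [lct_params()] vector
#' @param moiety `"CFMP"` or `"3PBA"`
#' @param topology `"parallel"` (default) or `"shared"`
#' @return 11 x 11 numeric matrix with dimnames
#' @export
build_rate_matrix <- function(params, moiety = c("CFMP", "3PBA"),
                              topology = c("parallel", "shared")) {
  moiety <- match.arg(moiety)
  topology <- match.arg(topology)
  p <- validate_lct_params(params)
  nm <- moiety_param_names(moiety)
  other <- moiety_param_names(if (moiety == "CFMP") "3PBA" else "CFMP")

  A <- matrix(0, 11, 11, dimnames = list(.lct_compartments,
                                         .lct_compartments))
  flow <- function(from, to, k) {
    A[to, from] <<- A[to, from] + k
    A[from, from] <<- A[from, from] - k
  }
  flow("D", "Din", p[["k_DDin"]])
  flow("GI", "B", p[["k_abs_oral"]])
  flow("RT", "B", p[["k_abs_inh"]])
  flow("B", "S", p[["k_BS"]])
  flow("S", "B", p[["k_SB"]])
  flow("B", "M", p[[nm$body[1]]])       # k_BM_<moiety>
  flow("B", "Mnm", p[[nm$body[2]]])     # k_BM_NO_<moiety>
  flow("M", "U", p[[nm$body[3]]])       # k_MU_<moiety>
  flow("M", "F", p[[nm$body[4]]])       # k_MF_<moiety>
  flow("Din", "B", p[["k_DinB"]])
  flow("Din", "MD", p[[nm$skin[1]]])    # k_DinMD_<moiety>
  flow("Din", "Mnm", p[[nm$skin[2]]])   # k_DinM_NO_<moiety>
  flow("MD", "M", p[[nm$skin[3]]])      # k_MDM_<moiety>
  if (topology == "shared") {
    flow("B", "Mnm", p[[other$body[1]]] + p[[other$body[2]]])
    flow("Din", "Mnm", p[[other$skin[1]]] + p[[other$skin[2]]])
  }
  A
}

# Entry compartment and dose scaling per route.
route_entry <- function(route, params) {
  switch(route,
    oral = list(comp = "GI", f = params[["f_abs_oral"]]),
    dermal = list(comp = "D", f = params[["f_abs_dermal"]]),
    inhalation = list(comp = "RT", f = params[["f_abs_inh"]]),
    systemic = list(comp = "B", f = 1),
    stop("unknown route: ", route))
}

#' Simulate the model over an exposure schedule
#'
#' Exact solution of the constant-coefficient linear system: within each
#' stretch of piecewise-constant input the state is advanced with the
#' matrix exponential of the (input-augmented) rate matrix; boluses are
#' instantaneous state increments scaled by the route's absorption
#' fraction, and a dermal `surface_removal` event zeroes the skin
#' surface deposit (the washed-off amount is tracked).
#'
#' @param schedule [lct_schedule()]
#' @param params [lct_params()]
#' @param moiety `"CFMP"` or `"3PBA"`
#' @param output_times times (h) at which the state is reported; must
#'   lie within the schedule horizon. Events at an output time are
#'   applied before the state is recorded.
#' @param topology see [build_rate_matrix()]
#' @return object of class `lct_sim`: list with `time`, `states`
#'   (length(time) x 11 matrix, pmol/kg bw), `QU` (urinary excretion
#'   rate, `M(t) * k_MU`, pmol/kg bw/h), `input_cum` (cumulative
#'   absorbed-side input) and `removed_cum` (cumulative washed-off
#'   surface deposit) at the output times
#' @export
propagate <- function(schedule, params, moiety = c("CFMP", "3PBA"),
                      output_times, topology = c("parallel", "shared")) {
  moiety <- match.arg(moiety)
  topology <- match.arg(topology)
  p <- validate_lct_params(params)
  if (!inherits(schedule, "lct_schedule")) stop("not an lct_schedule")
  horizon <- attr(schedule, "horizon")
  output_times <- as.numeric(output_times)
  if (any(output_times < 0) || any(output_times > horizon + 1e-9))
    stop("output_times outside the schedule horizon")
  A <- build_rate_matrix(p, moiety, topology)

  ev <- as.data.frame(schedule)
  bol <- ev[ev$duration == 0 & ev$amount > 0, , drop = FALSE]
  inf <- ev[ev$duration > 0 & ev$amount > 0, , drop = FALSE]
  washes <- sort(unique(ev$surface_removal[!is.na(ev$surface_removal)]))

  brk <- sort(unique(c(0, output_times, bol$t_start, washes,
                       inf$t_start, inf$t_start + inf$duration)))
  n <- length(.lct_compartments)
  x <- numeric(n)
  names(x) <- .lct_compartments
  input_cum <- 0
  removed_cum <- 0

  out_idx <- match(round(output_times, 10), round(brk, 10))
  states <- matrix(NA_real_, length(brk), n,
                   dimnames = list(NULL, .lct_compartments))
  inputs <- removed <- numeric(length(brk))

  # constant input vector g(t) for the open interval starting at t
  g_at <- function(t) {
    g <- numeric(n)
    if (nrow(inf)) {
      act <- inf$t_start <= t + 1e-12 & t < inf$t_start + inf$duration - 1e-12
      for (i in which(act)) {
        en <- route_entry(inf$route[i], p)
        g[match(en$comp, .lct_compartments)] <-
          g[match(en$comp, .lct_compartments)] + en$f * inf$amount[i]
      }
    }
    g
  }

  cache <- new.env(parent = emptyenv())
  step <- function(x, g, dt) {
    if (dt == 0) return(x)
    if (all(g == 0)) {
      key <- paste0("h", signif(dt, 14))
      E <- cache[[key]]
      if (is.null(E)) {
        E <- as.matrix(Matrix::expm(A * dt))
        cache[[key]] <- E
      }
      out <- E %*% x
    } else {
      key <- paste0("g", signif(dt, 14), "_", paste(signif(g, 14),
                                                    collapse = ","))
      E <- cache[[key]]
      if (is.null(E)) {
        Aug <- rbind(cbind(A, g), 0)
        E <- as.matrix(Matrix::expm(Aug * dt))
        cache[[key]] <- E
      }
      out <- E[1:n, 1:n] %*% x + E[1:n, n + 1]
    }
    if (any(!is.finite(out)))
      stop("non-finite matrix exponential propagation (dt = ", dt, ")")
    drop(out)
  }

  for (k in seq_along(brk)) {
    t_k <- brk[k]
    if (k > 1) {
      dt <- t_k - brk[k - 1]
      g <- g_at(brk[k - 1])
      x <- step(x, g, dt)
      input_cum <- input_cum + sum(g) * dt
    }
    # events at t_k: wash first, then boluses
    if (length(washes) && any(abs(washes - t_k) < 1e-9)) {
      removed_cum <- removed_cum + x[["D"]]
      x[["D"]] <- 0
    }
    if (nrow(bol)) {
      hit <- which(abs(bol$t_start - t_k) < 1e-9)
      for (i in hit) {
        en <- route_entry(bol$route[i], p)
        x[[en$comp]] <- x[[en$comp]] + en$f * bol$amount[i]
        input_cum <- input_cum + en$f * bol$amount[i]
      }
    }
    states[k, ] <- x
    inputs[k] <- input_cum
    removed[k] <- removed_cum
  }

  nm <- moiety_param_names(moiety)
  res <- list(
    time = output_times,
    states = states[out_idx, , drop = FALSE],
    QU = states[out_idx, "M"] * p[[nm$body[3]]],
    input_cum = inputs[out_idx],
    removed_cum = removed[out_idx],
    params = p, moiety = moiety, topology = topology,
    schedule = schedule
  )
  class(res) <- "lct_sim"
  res
}

#' @exportS3Method base::print
print.lct_sim <- function(x, ...) {
  cat("<lct_sim> ", x$moiety, " sub-model, ", length(x$time),
      " time points over [", min(x$time), ", ", max(x$time), "] h\n",
      sep = "")
  invisible(x)
}

#' Urinary amounts over collection intervals
#'
#' Computes `U(t1) - U(t0)` exactly for each interval by propagating the
#' model to the interval endpoints.
#'
#' @param params,schedule,moiety,topology as in [propagate()]
#' @param intervals two-column matrix (or data.frame) of start/end times
#'   in hours
#' @return numeric vector of per-interval urinary metabolite amounts
#'   (pmol/kg bw)
#' @export
urine_intervals <- function(params, schedule, intervals,
                            moiety = c("CFMP", "3PBA"),
                            topology = c("parallel", "shared")) {
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2 || any(intervals[, 2] < intervals[, 1]))
    stop("intervals must be a two-column matrix with end >= start")
  tt <- sort(unique(as.numeric(intervals)))
  sim <- propagate(schedule, params, moiety, tt, topology)
  U <- stats::setNames(sim$states[, "U"], round(tt, 10))
  U[as.character(round(intervals[, 2], 10))] -
    U[as.character(round(intervals[, 1], 10))]
}

#' Blood metabolite burden at sampling times
#'
#' The blood observable of the volunteer studies is the body burden of
#' the circulating metabolite, `M(t)` per kg bw.
#'
#' @inheritParams urine_intervals
#' @param times sampling times (h)
#' @return numeric vector of `M(t)` (pmol/kg bw)
#' @export
blood_metabolite <- function(params, schedule, times,
                             moiety = c("CFMP", "3PBA"),
                             topology = c("parallel", "shared")) {
  sim <- propagate(schedule, params, moiety, sort(unique(times)), topology)
  sim$states[match(round(times, 10), round(sim$time, 10)), "M"]
}

#' Impulse-response matrix from dose bins to urine collections
#'
#' Because the model is linear and time-invariant, the urinary amount in
#' a collection interval due to a unit bolus delivered at bin time
#' `t_j` equals `Uresp(end - t_j) - Uresp(start - t_j)`, where `Uresp`
#' is the cumulative urinary response to a unit bolus at time zero.
#' Column `j` of the returned matrix maps a unit dose (1 pmol/kg bw) in
#' bin `j` to the amount recovered in each collection interval, so
#' `G %*% doses` reproduces a full forward simulation of any bolus dose
#' profile on those bins.
#'
#' @param params [lct_params()]
#' @param route exposure route of the dose bins
#' @param bin_times bolus times of the dose bins (h)
#' @param intervals two-column matrix of urine-collection intervals (h);
#'   intervals must not overlap
#' @param moiety,topology see [propagate()]
#' @return `nrow(intervals)` x `length(bin_times)` non-negative matrix
#' @export
impulse_response_matrix <- function(params, route, bin_times, intervals,
                                    moiety = c("CFMP", "3PBA"),
                                    topology = c("parallel", "shared")) {
  moiety <- match.arg(moiety)
  topology <- match.arg(topology)
  intervals <- as.matrix(intervals)
  if (ncol(intervals) != 2 || any(intervals[, 2] < intervals[, 1]))
    stop("intervals must be a two-column matrix with end >= start")
  o <- order(intervals[, 1])
  if (any(intervals[o, 1][-1] < intervals[o, 2][-nrow(intervals)] - 1e-9))
    stop("overlapping collection intervals")
  if (any(bin_times < 0)) stop("negative bin time")

  lags <- outer(as.numeric(intervals), bin_times, "-")
  dim(lags) <- c(nrow(intervals), 2, length(bin_times))
  pos <- sort(unique(pmax(as.numeric(lags), 0)))
  sched <- schedule_bolus(route, 1, times = 0, horizon = max(pos))
  sim <- propagate(sched, params, moiety, pos, topology)
  Uresp <- stats::setNames(sim$states[, "U"], round(pos, 10))
  lookup <- function(tau) unname(Uresp[as.character(round(pmax(tau, 0), 10))])
  G <- matrix(0, nrow(intervals), length(bin_times))
  for (j in seq_along(bin_times))
    G[, j] <- lookup(lags[, 2, j]) - lookup(lags[, 1, j])
  G[G < 0] <- 0  # clip tiny negative round-off
  G
}

#' Asymptotic urinary recovery fraction (closed form)
#'
#' For oral (or systemic, `f = 1`) dosing the fraction of the absorbed
#' dose ultimately excreted in urine as the metabolite is
#' `f * k_BM / (k_BM + k_BM_NO) * k_MU / (k_MU + k_MF)`; the storage
#' compartment returns all of its mass and does not change the limit.
#'
#' @param params [lct_params()]
#' @param moiety metabolite
#' @param f absorbed fraction applied to the dose (e.g. `f_abs_oral`)
#' @return scalar fraction in \[0, 1\]
#' @export
asymptotic_urinary_fraction <- function(params, moiety = c("CFMP", "3PBA"),
                                        f = params[["f_abs_oral"]]) {
  moiety <- match.arg(moiety)
  nm <- moiety_param_names(moiety)$body
  kbm <- params[[nm[1]]]; kno <- params[[nm[2]]]
  kmu <- params[[nm[3]]]; kmf <- params[[nm[4]]]
  if (kbm + kno == 0 || kmu + kmf == 0) return(0)
  f * kbm / (kbm + kno) * kmu / (kmu + kmf)
}

#' Tidy export of a simulated trajectory
#'
#' @param sim an `lct_sim`
#' @param path optional CSV path; when given the data.frame is written
#' @return data.frame `time_h, compartment, moiety, value_pmol_per_kg`
#' @export
sim_to_tidy <- function(sim, path = NULL) {
  df <- data.frame(
    time_h = rep(sim$time, times = ncol(sim$states)),
    compartment = rep(colnames(sim$states), each = length(sim$time)),
    moiety = sim$moiety,
    value_pmol_per_kg = as.numeric(sim$states)
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
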