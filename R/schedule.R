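# Exposure schedules: timed dose events per route.

.lct_routes <- c("oral", "dermal", "inhalation", "systemic")

#' Create a single exposure event
#'
#' @param route one of `"oral"`, `"dermal"`, `"inhalation"`,
#'   `"systemic"` (systemic delivers directly into blood)
#' @param t_start start time, hours from the study origin
#' @param amount dose in pmol/kg bw for a bolus (`duration = 0`) or a
#'   constant rate in pmol/kg bw/h over `duration` hours
#' @param duration hours; 0 means an instantaneous bolus
#' @param surface_removal time (h) at which a dermal surface deposit is
#'   washed off (the D compartment is zeroed); `NA` for none
#' @return one-row data.frame
#' @export
lct_event <- function(route, t_start, amount, duration = 0,
                      surface_removal = NA_real_) {
  route <- match.arg(route, .lct_routes)
  stopifnot(t_start >= 0, amount >= 0, duration >= 0)
  if (!is.na(surface_removal) && route != "dermal")
    stop("surface_removal applies to dermal events only")
  data.frame(route = route, t_start = t_start, duration = duration,
             amount = amount, surface_removal = surface_removal)
}

#' Assemble an exposure schedule
#'
#' @param ... events from [lct_event()] (or data.frames of events)
#' @param horizon simulation horizon in hours; defaults to the latest
#'   event end (plus removal times)
#' @return object of class `lct_schedule`: a data.frame of events sorted
#'   by start time with a `horizon` attribute
#' @export
lct_schedule <- function(..., horizon = NULL) {
  ev <- do.call(rbind, list(...))
  if (is.null(ev) || nrow(ev) == 0)
    ev <- lct_event("oral", 0, 0)[0, ]
  ev <- ev[order(ev$t_start), , drop = FALSE]
  rownames(ev) <- NULL
  ends <- c(0, ev$t_start + ev$duration,
            ev$surface_removal[!is.na(ev$surface_removal)])
  if (is.null(horizon)) horizon <- max(ends)
  if (horizon < max(ends))
    stop("horizon earlier than the last scheduled event")
  structure(ev, horizon = horizon, class = c("lct_schedule", "data.frame"))
}

#' Shorthand schedules
#'
#' `schedule_bolus()` builds a single-event schedule;
#' `schedule_repeated_bolus()` places the same bolus at several times
#' (e.g. hourly occupational doses).
#'
#' @param route exposure route
#' @param amount pmol/kg bw per bolus
#' @param times start times (h)
#' @param horizon simulation horizon (h)
#' @param surface_removal dermal wash time, if any
#' @return `lct_schedule`
#' @export
schedule_bolus <- function(route, amount, times = 0, horizon = NULL,
                           surface_removal = NA_real_) {
  ev <- do.call(rbind, lapply(times, function(t0)
    lct_event(route, t0, amount, surface_removal = surface_removal)))
  lct_schedule(ev, horizon = horizon)
}

#' @rdname schedule_bolus
#' @export
schedule_repeated_bolus <- schedule_bolus

#' Read / write exposure schedules as CSV
#'
#' Columns: `route, t_start_h, duration_h, amount, surface_removal_h`.
#' @param x an `lct_schedule`
#' @param path file path
#' @return `read_schedule_csv` returns an `lct_schedule`
#' @export
write_schedule_csv <- function(x, path) {
  df <- data.frame(route = x$route, t_start_h = x$t_start,
                   duration_h = x$duration, amount = x$amount,
                   surface_removal_h = x$surface_removal)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @param horizon optional horizon override when reading
#' @export
read_schedule_csv <- function(path, horizon = NULL) {
  df <- utils::read.csv(path)
  ev <- do.call(rbind, lapply(seq_len(nrow(df)), function(i)
    lct_event(df$route[i], df$t_start_h[i], df$amount[i],
              duration = df$duration_h[i],
              surface_removal = df$surface_removal_h[i])))
  lct_schedule(ev, horizon = horizon)
}
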