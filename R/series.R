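# Observed biomarker series: blood points and urine-interval amounts,
# with below-LOQ censoring, tied to the exposure schedule of the study.

#' Construct an observed biomarker series
#'
#' @param data data.frame with columns `matrix` (`"blood"` or
#'   `"urine"`), `analyte` (`"CFMP"` or `"3PBA"`), `t_start_h`,
#'   `t_end_h` (equal to `t_start_h` for blood points),
#'   `value_pmol_per_kg` (the measured value, or the limit of
#'   quantification for censored rows) and `censored` (logical)
#' @param schedule the [lct_schedule()] of the study exposures
#' @param subject subject identifier
#' @return object of class `lct_series`
#' @export
lct_series <- function(data, schedule, subject = "S1") {
  need <- c("matrix", "analyte", "t_start_h", "t_end_h",
            "value_pmol_per_kg", "censored")
  if (!all(need %in% names(data)))
    stop("series data must have columns: ", paste(need, collapse = ", "))
  if (!all(data$matrix %in% c("blood", "urine")))
    stop("matrix must be 'blood' or 'urine'")
  if (!all(data$analyte %in% c("CFMP", "3PBA")))
    stop("analyte must be 'CFMP' or '3PBA'")
  if (any(data$value_pmol_per_kg < 0)) stop("negative observed value")
  if (any(data$t_end_h < data$t_start_h)) stop("interval end before start")
  for (an in unique(data$analyte)) {
    iv <- data[data$matrix == "urine" & data$analyte == an, , drop = FALSE]
    if (nrow(iv) > 1) {
      iv <- iv[order(iv$t_start_h), ]
      if (any(iv$t_start_h[-1] < iv$t_end_h[-nrow(iv)] - 1e-9))
        stop("overlapping urine intervals for analyte ", an)
    }
  }
  structure(list(data = data, schedule = schedule, subject = subject),
            class = "lct_series")
}

#' @exportS3Method base::print
print.lct_series <- function(x, ...) {
  cat("<lct_series> subject ", x$subject, ": ",
      sum(x$data$matrix == "blood"), " blood points, ",
      sum(x$data$matrix == "urine"), " urine intervals (",
      sum(x$data$censored), " censored)\n", sep = "")
  invisible(x)
}

#' Model predictions aligned with an observed series
#'
#' Simulates the study schedule and returns the model's value for every
#' observation row: `M(t)` for blood points, `U` increments for urine
#' intervals.
#'
#' @param params [lct_params()]
#' @param series [lct_series()]
#' @param topology see [build_rate_matrix()]
#' @return numeric vector, one prediction per row of `series$data`
#' @export
predict_series <- function(params, series,
                           topology = c("parallel", "shared")) {
  topology <- match.arg(topology)
  d <- series$data
  pred <- numeric(nrow(d))
  for (an in unique(d$analyte)) {
    rows <- which(d$analyte == an)
    tt <- sort(unique(c(d$t_start_h[rows], d$t_end_h[rows])))
    sim <- propagate(series$schedule, params, an, tt, topology)
    U <- stats::setNames(sim$states[, "U"], round(tt, 10))
    M <- stats::setNames(sim$states[, "M"], round(tt, 10))
    for (i in rows) {
      pred[i] <- if (d$matrix[i] == "blood")
        M[[as.character(round(d$t_start_h[i], 10))]]
      else
        U[[as.character(round(d$t_end_h[i], 10))]] -
          U[[as.character(round(d$t_start_h[i], 10))]]
    }
  }
  pred
}

#' Read / write observed series as CSV
#'
#' Columns: `subject, matrix, analyte, t_start_h, t_end_h,
#' value_pmol_per_kg, censored`. The exposure schedule travels in a
#' companion schedule CSV (see [write_schedule_csv()]).
#'
#' @param x an `lct_series`
#' @param path CSV path
#' @export
write_series_csv <- function(x, path) {
  df <- cbind(subject = x$subject, x$data)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @param schedule schedule to attach on read
#' @export
read_series_csv <- function(path, schedule) {
  df <- utils::read.csv(path)
  subject <- if ("subject" %in% names(df)) df$subject[1] else "S1"
  df$subject <- NULL
  df$censored <- as.logical(df$censored)
  lct_series(df, schedule, subject)
}
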