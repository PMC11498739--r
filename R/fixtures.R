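# Packaged fixtures: the published per-volunteer parameter summaries
# (mean +/- SD) from the oral and dermal volunteer studies, loadable as
# degenerate ensembles for Monte-Carlo sampling.

.fixture_md5 <- c(
  table2 = "99540c3aaf0fb7be8f538dd032568ba8",
  table3 = "03becfc5d3ec63879e7429255ae5c3b5"
)

fixture_path <- function(which) {
  file <- switch(which,
    table2 = "table2_oral_parameters.csv",
    table3 = "table3_dermal_parameters.csv",
    stop("unknown fixture: ", which))
  system.file("extdata", file, package = "cyhalotk", mustWork = TRUE)
}

#' Load the packaged volunteer parameter tables
#'
#' Returns the published mean and SD of every model parameter fitted
#' per volunteer: `"table2"` holds the oral-study parameters (oral
#' absorption, storage exchange and both metabolites' body-side
#' branches, volunteers 1-7); `"table3"` holds the dermal-specific
#' parameters (volunteers 2, 3, 5 and 6; the two remaining volunteers'
#' levels were too low to model). The files are integrity-checked
#' against an md5 manifest.
#'
#' @param which `"table2"` or `"table3"`
#' @return data.frame `volunteer, parameter, mean, sd`
#' @export
load_fixture_parameters <- function(which = c("table2", "table3")) {
  which <- match.arg(which)
  path <- fixture_path(which)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[which])))
    stop("fixture corruption: ", basename(path),
         " md5 ", md5, " != manifest ", .fixture_md5[which])
  df <- utils::read.csv(path)
  unknown <- setdiff(df$parameter, lct_param_names())
  if (length(unknown))
    stop("fixture has unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  df
}

#' Per-volunteer parameter summary from a fixture
#'
#' @param which fixture name
#' @param volunteer volunteer id as printed in the table
#' @return named list with `mean` and `sd` vectors over the fixture's
#'   parameters
#' @export
fixture_volunteer <- function(which, volunteer) {
  df <- load_fixture_parameters(which)
  sub <- df[df$volunteer == volunteer, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no volunteer '", volunteer, "' in ", which)
  list(mean = stats::setNames(sub$mean, sub$parameter),
       sd = stats::setNames(sub$sd, sub$parameter))
}

#' Full parameter vector at a volunteer's fitted means
#'
#' Combines the oral-study means with (when available) the dermal-
#' specific means for one volunteer into a complete [lct_params()].
#'
#' @param volunteer volunteer id (1-7; dermal values exist for 2, 3, 5
#'   and 6)
#' @param dermal include the dermal-specific parameters when published
#' @return `lct_params`
#' @export
fixture_params <- function(volunteer, dermal = TRUE) {
  v <- fixture_volunteer("table2", volunteer)$mean
  if (dermal &&
      volunteer %in% unique(load_fixture_parameters("table3")$volunteer))
    v <- c(v, fixture_volunteer("table3", volunteer)$mean)
  lct_params(.values = v)
}

# moment-matched lognormal: preserves the arithmetic mean and SD
lognormal_from_moments <- function(mean, sd) {
  sigma2 <- ifelse(mean > 0, log(1 + (sd / mean)^2), 0)
  list(mu = ifelse(mean > 0, log(mean) - sigma2 / 2, -Inf),
       sigma = sqrt(sigma2))
}

#' Build degenerate ensembles from the published summaries
#'
#' Converts the per-volunteer printed means +/- SD into `lct_ensemble`
#' objects carrying moment-matched lognormal (mu, sigma) per parameter,
#' ready for [sample_parameters()]. `which = "combined"` merges the
#' oral and dermal tables for the volunteers present in both (needed
#' for dermal-route reconstruction).
#'
#' @param which `"table2"`, `"table3"` or `"combined"`
#' @return named list of `lct_ensemble` objects, one per volunteer
#' @export
fixture_ensembles <- function(which = c("table2", "table3", "combined")) {
  which <- match.arg(which)
  tabs <- if (which == "combined") c("table2", "table3") else which
  per_vol <- list()
  for (tb in tabs) {
    df <- load_fixture_parameters(tb)
    for (v in unique(df$volunteer)) {
      fx <- fixture_volunteer(tb, v)
      key <- as.character(v)
      per_vol[[key]] <- list(
        mean = c(per_vol[[key]]$mean, fx$mean),
        sd = c(per_vol[[key]]$sd, fx$sd))
    }
  }
  if (which == "combined") {
    both <- names(which(vapply(per_vol, function(x)
      all(c("k_abs_oral", "k_DinB") %in% names(x$mean)), TRUE)))
    per_vol <- per_vol[both]
  }
  out <- lapply(names(per_vol), function(v) {
    m <- per_vol[[v]]$mean; s <- per_vol[[v]]$sd
    ln <- lognormal_from_moments(m, s)
    structure(list(
      draws = NULL, errors = numeric(0), free = names(m),
      fixed = lct_params(.values = m),
      summary = list(mean = m, sd = s),
      lognormal = list(mu = ln$mu, sigma = ln$sigma),
      provenance = list(subject = paste0("volunteer-", v),
                        stage = paste0("fixture-", which), seed = NA)
    ), class = "lct_ensemble")
  })
  stats::setNames(out, names(per_vol))
}

#' Write / read an ensemble as JSON
#'
#' Stores draws (when present), summaries, lognormal parameters, the
#' fixed base vector and provenance; round-trips losslessly.
#'
#' @param x `lct_ensemble`
#' @param path JSON path
#' @export
write_ensemble_json <- function(x, path) {
  jsonlite::write_json(list(
    draws = x$draws, errors = x$errors, free = x$free,
    fixed = as.list(unclass(x$fixed)),
    summary = lapply(x$summary, as.list),
    lognormal = lapply(x$lognormal, as.list),
    provenance = x$provenance
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ensemble_json
#' @export
read_ensemble_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  draws <- j$draws
  if (!is.null(draws)) {
    draws <- as.matrix(draws)
    colnames(draws) <- j$free
  }
  structure(list(
    draws = draws, errors = as.numeric(j$errors), free = j$free,
    fixed = lct_params(.values = unlist(j$fixed)),
    summary = lapply(j$summary, unlist),
    lognormal = lapply(j$lognormal, unlist),
    provenance = j$provenance
  ), class = "lct_ensemble")
}
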