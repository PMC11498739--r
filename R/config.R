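# Run configuration: flat key-value settings with strict key checking,
# JSON-compatible on disk, and a logger that echoes every effective
# constant together with the seed.

.lct_config_defaults <- function() list(
  seed = 1L,
  n_sets = 1000L,        # accepted parameter sets per fit
  n_accept = 1000L,      # accepted dose profiles per reconstruction
  n_draws = 10000L,      # Monte-Carlo draws for the reference value
  error_cap = 0.20,      # fit acceptance, mean absolute relative dev.
  max_R = 0.05,          # reconstruction acceptance
  aoel_ng_kg_d = 630,
  body_weight_kg = 70.13,
  urine_volume_L = 1.086,
  topology = "parallel",
  delivery = "systemic"
)

#' Build a run configuration
#'
#' Starts from the package defaults and overrides named settings;
#' unknown keys and non-positive counts/caps are rejected.
#'
#' @param ... named overrides of the default settings
#' @return list of class `lct_config`
#' @export
lct_config <- function(...) {
  cfg <- .lct_config_defaults()
  override <- list(...)
  if (length(override)) {
    unknown <- setdiff(names(override), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(override)] <- override
  }
  for (key in c("n_sets", "n_accept", "n_draws", "error_cap", "max_R",
                "aoel_ng_kg_d", "body_weight_kg", "urine_volume_L"))
    if (cfg[[key]] <= 0) stop("config key ", key, " must be positive")
  if (!cfg$topology %in% c("parallel", "shared"))
    stop("topology must be 'parallel' or 'shared'")
  if (!cfg$delivery %in% c("systemic", "oral"))
    stop("delivery must be 'systemic' or 'oral'")
  structure(cfg, class = "lct_config")
}

#' @exportS3Method base::print
print.lct_config <- function(x, ...) {
  cat("<lct_config>\n")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Write / read a configuration as JSON
#'
#' @param cfg `lct_config`
#' @param path JSON path
#' @export
write_config_json <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  do.call(lct_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Log the effective configuration to a connection
#'
#' Echoes every setting (no hidden defaults) plus the package version;
#' analysis drivers call this at start-up so each run records its seed
#' and constants.
#'
#' @param cfg `lct_config`
#' @param con connection (default `stderr()`)
#' @export
log_config <- function(cfg, con = stderr()) {
  writeLines(c(
    paste0("cyhalotk ", as.character(utils::packageVersion("cyhalotk"))),
    vapply(names(cfg), function(nm)
      paste0("  ", nm, " = ", format(cfg[[nm]])), "")), con)
  invisible(cfg)
}
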