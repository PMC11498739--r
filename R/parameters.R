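# Parameter vector for the LCT compartmental model.
#
# Flat named-numeric representation: one entry per rate constant or
# absorption fraction of the conceptual model. Shared LCT-side
# parameters come first, then the CFMP and 3-PBA branch parameters and
# the dermal (internal skin) branch parameters per metabolite.

.lct_fraction_names <- c("f_abs_oral", "f_abs_dermal", "f_abs_inh")

.lct_rate_names <- c(
  "k_abs_oral", "k_DDin", "k_DinB", "k_abs_inh", "k_BS", "k_SB",
  "k_BM_CFMP", "k_BM_NO_CFMP", "k_MU_CFMP", "k_MF_CFMP",
  "k_BM_3PBA", "k_BM_NO_3PBA", "k_MU_3PBA", "k_MF_3PBA",
  "k_DinMD_CFMP", "k_DinM_NO_CFMP", "k_MDM_CFMP",
  "k_DinMD_3PBA", "k_DinM_NO_3PBA", "k_MDM_3PBA"
)

#' Names of all model parameters
#'
#' @return character vector: the three absorption fractions followed by
#'   the twenty first-order transfer rates (h^-1)
#' @export
lct_param_names <- function() c(.lct_fraction_names, .lct_rate_names)

#' Construct a model parameter vector
#'
#' All rates are first-order transfer constants in h^-1; fractions are
#' dimensionless in \[0, 1\]. Unspecified rates default to 0 except the
#' respiratory absorption rate, which defaults to a 1-minute half-life
#' (`60 * log(2)` h^-1). Dermal and inhalation absorption fractions
#' default to 1 (any absorption limitation is carried by `k_DDin` and
#' the surface-removal event, and the inhalation fraction is a
#' deliberate overestimate).
#'
#' @param ... named parameter values; names must be in
#'   [lct_param_names()]
#' @param .values optional named numeric vector/list merged before `...`
#' @return named numeric vector of class `lct_params`
#' @examples
#' p <- lct_params(f_abs_oral = 0.96, k_abs_oral = 2.3, k_BS = 0.06,
#'                 k_SB = 0.002, k_BM_CFMP = 0.03, k_BM_NO_CFMP = 0.03,
#'                 k_MU_CFMP = 0.40, k_MF_CFMP = 0.03)
#' @export
lct_params <- function(..., .values = NULL) {
  p <- stats::setNames(numeric(length(lct_param_names())), lct_param_names())
  p["f_abs_dermal"] <- 1
  p["f_abs_inh"] <- 1
  p["k_abs_inh"] <- 60 * log(2)
  override <- c(as.list(.values), list(...))
  if (length(override)) {
    nm <- names(override)
    if (is.null(nm) || any(nm == ""))
      stop("all parameter values must be named")
    unknown <- setdiff(nm, lct_param_names())
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[nm] <- unlist(override)
  }
  validate_lct_params(structure(p, class = "lct_params"))
}

#' Validate a parameter vector
#'
#' Checks completeness, non-negativity of rates and that fractions lie
#' in \[0, 1\].
#'
#' @param p object as returned by [lct_params()]
#' @return `p`, invisibly classed, or an error
#' @export
validate_lct_params <- function(p) {
  if (!all(lct_param_names() %in% names(p)))
    stop("parameter vector is missing entries: ",
         paste(setdiff(lct_param_names(), names(p)), collapse = ", "))
  p <- structure(p[lct_param_names()], class = "lct_params")
  if (any(!is.finite(p))) stop("non-finite parameter value")
  if (any(p[.lct_rate_names] < 0))
    stop("negative rate constant: ",
         paste(.lct_rate_names[p[.lct_rate_names] < 0], collapse = ", "))
  fr <- p[.lct_fraction_names]
  if (any(fr < 0 | fr > 1))
    stop("absorption fraction outside [0, 1]: ",
         paste(.lct_fraction_names[fr < 0 | fr > 1], collapse = ", "))
  p
}

#' @exportS3Method base::print
print.lct_params <- function(x, ...) {
  cat("<lct_params> (h^-1 rates; dimensionless fractions)\n")
  print(unclass(x), ...)
  invisible(x)
}

# Branch parameter names for one metabolite, body-side and skin-side.
moiety_param_names <- function(moiety = c("CFMP", "3PBA")) {
  moiety <- match.arg(moiety)
  suf <- if (moiety == "CFMP") "CFMP" else "3PBA"
  list(
    body = paste0(c("k_BM_", "k_BM_NO_", "k_MU_", "k_MF_"), suf),
    skin = paste0(c("k_DinMD_", "k_DinM_NO_", "k_MDM_"), suf)
  )
}

#' Parameter-name sets used in staged fitting
#'
#' `oral` is the set determined from the oral volunteer studies (shared
#' absorption/storage rates plus both metabolites' body-side branches);
#' `dermal` is the dermal-specific set determined afterwards with the
#' oral values held fixed.
#'
#' @param stage `"oral"` or `"dermal"`
#' @return character vector of parameter names
#' @export
lct_stage_params <- function(stage = c("oral", "dermal")) {
  stage <- match.arg(stage)
  if (stage == "oral")
    c("f_abs_oral", "k_abs_oral", "k_BS", "k_SB",
      moiety_param_names("CFMP")$body, moiety_param_names("3PBA")$body)
  else
    c("f_abs_dermal", "k_DDin", "k_DinB",
      moiety_param_names("CFMP")$skin, moiety_param_names("3PBA")$skin)
}
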