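#' Physico-chemical and regulatory constants
#'
#' Molecular weights (g/mol) of lambda-cyhalothrin (LCT) and its two
#' urinary metabolites, the EFSA Acceptable Operator Exposure Level
#' (AOEL), and the unit conversions used throughout the package.
#' Internal model units are pmol per kg body weight, time in hours.
#'
#' @format A named list:
#' \describe{
#'   \item{mw}{molecular weights, g/mol: `LCT` 449.85, `CFMP` 242.62,
#'     `PBA3` 214.22}
#'   \item{aoel_ng_kg_d}{systemic AOEL, 630 ng/kg bw/d}
#'   \item{aoel_pmol_kg_d}{the same dose in molar units,
#'     630/449.85 × 1000 ≈ 1400 pmol/kg bw/d}
#' }
#' @export
lct_constants <- function() {
  mw <- c(LCT = 449.85, CFMP = 242.62, PBA3 = 214.22)
  list(
    mw = mw,
    aoel_ng_kg_d = 630,
    aoel_pmol_kg_d = 630 / mw[["LCT"]] * 1000
  )
}

#' Convert a mass dose of LCT to molar units
#'
#' @param ng nanograms (per kg bw, or absolute — the scale is preserved)
#' @return picomoles on the same per-kg basis
#' @export
lct_ng_to_pmol <- function(ng) ng / lct_constants()$mw[["LCT"]] * 1000

#' Convert a molar metabolite amount to mass units
#'
#' @param pmol picomoles of metabolite
#' @param analyte `"CFMP"` or `"3PBA"`
#' @return nanograms
#' @export
metabolite_pmol_to_ng <- function(pmol, analyte = c("CFMP", "3PBA")) {
  analyte <- match.arg(analyte)
  mw <- lct_constants()$mw[[if (analyte == "CFMP") "CFMP" else "PBA3"]]
  pmol * mw / 1000
}

#' Formulation and field-application constants for Matador 120EC
#'
#' The commercial emulsifiable concentrate contains 120 g/L LCT
#' (0.267 mol/L); the label application rate is 104 mL/ha, i.e.
#' 12.48 g active ingredient per hectare or 1.04 nL of formulation per
#' cm2 of treated surface. A hypothetical strawberry leaf is 100 cm2
#' and whole-hand contact transfers 2% of a surface deposit.
#'
#' @param mass_conc_g_L LCT mass concentration of the formulation, g/L
#' @param application_mL_ha volumetric application rate, mL/ha
#' @param leaf_area_cm2 assumed area of one strawberry leaf, cm2
#' @param hand_transfer_fraction surface-to-hand transfer fraction
#' @return object of class `lct_formulation` with derived fields
#'   `molarity_mol_L`, `areal_rate_nL_cm2` and
#'   `application_g_ha` (mass rate in g AI/ha)
#' @export
lct_formulation <- function(mass_conc_g_L = 120,
                            application_mL_ha = 104,
                            leaf_area_cm2 = 100,
                            hand_transfer_fraction = 0.02) {
  stopifnot(mass_conc_g_L >= 0, application_mL_ha >= 0,
            leaf_area_cm2 >= 0,
            hand_transfer_fraction >= 0, hand_transfer_fraction <= 1)
  mw <- lct_constants()$mw[["LCT"]]
  structure(list(
    mass_conc_g_L = mass_conc_g_L,
    molarity_mol_L = mass_conc_g_L / mw,
    application_mL_ha = application_mL_ha,
    application_g_ha = application_mL_ha / 1000 * mass_conc_g_L,
    # 1 ha = 1e8 cm2; mL/ha -> nL/cm2 is a factor 1e6/1e8
    areal_rate_nL_cm2 = application_mL_ha * 1e6 / 1e8,
    leaf_area_cm2 = leaf_area_cm2,
    hand_transfer_fraction = hand_transfer_fraction
  ), class = "lct_formulation")
}

#' Ventilation model for inhalation back-calculation
#'
#' Default: 20 breaths per minute at 500 mL tidal volume, i.e. a minute
#' ventilation of 10 L/min = 0.6 m3/h, with a deliberately overestimated
#' pulmonary absorption fraction of 100%.
#'
#' @param breaths_per_min respiratory frequency
#' @param tidal_volume_L volume per breath, litres
#' @param absorption_fraction fraction of inhaled LCT absorbed
#' @return object of class `lct_ventilation` with derived
#'   `ventilation_m3_h`
#' @export
lct_ventilation <- function(breaths_per_min = 20, tidal_volume_L = 0.5,
                            absorption_fraction = 1.0) {
  stopifnot(breaths_per_min > 0, tidal_volume_L > 0,
            absorption_fraction > 0, absorption_fraction <= 1)
  structure(list(
    breaths_per_min = breaths_per_min,
    tidal_volume_L = tidal_volume_L,
    ventilation_m3_h = breaths_per_min * tidal_volume_L * 60 / 1000,
    absorption_fraction = absorption_fraction
  ), class = "lct_ventilation")
}
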