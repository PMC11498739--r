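# Exposure-plausibility arithmetic: dermal leaf-contact loading,
# back-calculation of the dermal dose required to explain observed
# excretion, and inhalation air-concentration back-calculation with
# application-rate normalization. Pure functions of their inputs.

#' LCT load on one strawberry leaf after application
#'
#' Volume of formulation deposited per leaf (leaf area x areal
#' application rate) and the corresponding molar amount of LCT.
#'
#' @param constants [lct_formulation()]
#' @return list: `volume_uL` (formulation per leaf) and `amount_nmol`
#'   (LCT per leaf)
#' @examples
#' leaf_load()  # ~0.104 uL and ~28 nmol per 100 cm2 leaf
#' @export
leaf_load <- function(constants = lct_formulation()) {
  vol_nL <- constants$leaf_area_cm2 * constants$areal_rate_nL_cm2
  list(volume_uL = vol_nL / 1000,
       amount_nmol = vol_nL * 1e-9 * constants$molarity_mol_L * 1e9)
}

#' Number of leaves to handle for a target dermal dose
#'
#' @param target_dose_umol whole-body dermal dose to explain, umol LCT
#' @param transfer_fraction surface-to-hand transfer (1 = complete;
#'   0.02 = the whole-hand contact estimate)
#' @param constants [lct_formulation()]
#' @return list: `count` (exact) and `count_reported` (rounded to 2
#'   significant figures, the convention for these "around" estimates)
#' @export
leaves_required <- function(target_dose_umol,
                            transfer_fraction = 1,
                            constants = lct_formulation()) {
  stopifnot(target_dose_umol > 0)
  if (transfer_fraction <= 0)
    stop("zero transfer fraction: leaf requirement is unbounded")
  stopifnot(transfer_fraction <= 1)
  per_leaf_umol <- leaf_load(constants)$amount_nmol / 1000
  n <- target_dose_umol / (per_leaf_umol * transfer_fraction)
  list(count = n, count_reported = signif(n, 2))
}

#' Dermal dose implied by a worker/volunteer excretion-rate ratio
#'
#' Scales the controlled dermal dose given to volunteers by the ratio
#' of the worker's peak urinary excretion rate to the volunteers'
#' maximum, then converts to a whole-body dose and the equivalent
#' volume of undiluted formulation.
#'
#' @param peak_ratio worker peak excretion rate / volunteer maximum
#' @param volunteer_dose_umol_kg controlled dermal dose, umol/kg bw
#' @param body_weight_kg worker body weight
#' @param constants [lct_formulation()]
#' @return list: `dose_umol_kg`, `dose_umol` (whole body),
#'   `volume_uL` (pure formulation holding that amount)
#' @export
dermal_dose_from_excretion_ratio <- function(peak_ratio,
                                             volunteer_dose_umol_kg,
                                             body_weight_kg,
                                             constants = lct_formulation()) {
  stopifnot(peak_ratio >= 0, volunteer_dose_umol_kg > 0,
            body_weight_kg > 0)
  per_kg <- peak_ratio * volunteer_dose_umol_kg
  total <- per_kg * body_weight_kg
  list(dose_umol_kg = per_kg, dose_umol = total,
       volume_uL = formulation_volume(total, constants))
}

#' Volume of formulation containing a given amount of LCT
#'
#' @param dose_umol LCT amount, umol
#' @param constants [lct_formulation()]
#' @return volume in uL
#' @export
formulation_volume <- function(dose_umol, constants = lct_formulation()) {
  stopifnot(dose_umol >= 0)
  dose_umol / constants$molarity_mol_L  # umol / (umol/uL) = uL
}

#' Air concentration required for an hourly absorbed dose
#'
#' Back-calculates the airborne LCT concentration that would deliver a
#' given hourly absorbed dose through breathing, assuming complete
#' pulmonary absorption by default.
#'
#' @param hourly_dose_ng absorbed dose per hour, ng (whole body)
#' @param ventilation [lct_ventilation()]
#' @return concentration in ug/m3
#' @export
air_concentration <- function(hourly_dose_ng,
                              ventilation = lct_ventilation()) {
  stopifnot(hourly_dose_ng >= 0)
  hourly_dose_ng /
    (ventilation$ventilation_m3_h * ventilation$absorption_fraction) / 1000
}

#' Normalize an air concentration by the application rate
#'
#' Expresses a concentration per 1 kg of active ingredient applied per
#' hectare, the convention for comparing field studies.
#'
#' @param conc_ug_m3 air concentration, ug/m3
#' @param application_g_ha application rate, g AI/ha (default the
#'   Matador label rate, 12.48)
#' @return ug/m3 per AR 1 kg AI/ha
#' @export
normalize_by_ar <- function(conc_ug_m3,
                            application_g_ha =
                              lct_formulation()$application_g_ha) {
  if (application_g_ha <= 0) stop("application rate must be positive")
  conc_ug_m3 / (application_g_ha / 1000)
}
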