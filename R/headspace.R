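#' Jar geometry for headspace equilibration
#'
#' Describes the sealed jar used for dissolved-gas sampling: bulk sediment and
#' distilled water are placed in a gas-tight jar, leaving a gas headspace that
#' equilibrates with the aqueous phase. Defaults follow the field protocol used
#' throughout this package: 133 mL of sediment in a 600 mL jar with 200 mL of
#' water and 200 mL of headspace, sediment porosity 0.8 (uncompacted mud).
#'
#' @param jar_volume Total jar volume, mL.
#' @param sediment_volume Bulk sediment volume placed in the jar, mL.
#' @param water_added Distilled water added, mL.
#' @param headspace_volume Gas headspace formed, mL.
#' @param porosity Sediment porosity, fraction in (0, 1); the porewater volume
#'   is `sediment_volume * porosity`.
#' @return An object of class `jar_geometry`.
#' @examples
#' jar_geometry()
#' @export
jar_geometry <- function(jar_volume = 600, sediment_volume = 133,
                         water_added = 200, headspace_volume = 200,
                         porosity = 0.8) {
  for (nm in c("jar_volume", "sediment_volume", "water_added", "headspace_volume"))
    stop_if_not_scalar_number(get(nm), nm, positive = TRUE)
  check_porosity(porosity)
  if (sediment_volume + water_added + headspace_volume >
        jar_volume * (1 + 1e-6)) {
    stop("sediment + water + headspace volumes exceed the jar volume",
         call. = FALSE)
  }
  structure(list(jar_volume = jar_volume, sediment_volume = sediment_volume,
                 water_added = water_added, headspace_volume = headspace_volume,
                 porosity = porosity),
            class = "jar_geometry")
}

#' Laboratory equilibration conditions and gas constants
#'
#' Physical constants needed to partition methane between the jar headspace
#' and the aqueous phase: ideal-gas conditions for the headspace and a Henry
#' solubility constant with a van 't Hoff temperature correction for the
#' dissolved fraction. The defaults (21 degrees C lab, 1 atm, K_H = 1.4e-3
#' mol L^-1 atm^-1 at 298.15 K with a 1700 K van 't Hoff parameter) are
#' standard methane values for fresh water; salinity effects are neglected
#' because the jars receive distilled water.
#'
#' @param temperature Equilibration temperature, K.
#' @param pressure Total headspace pressure, atm.
#' @param gas_constant Ideal-gas constant, L atm mol^-1 K^-1.
#' @param henry_constant Methane Henry solubility at `henry_ref_temperature`,
#'   mol L^-1 atm^-1.
#' @param henry_ref_temperature Reference temperature for `henry_constant`, K.
#' @param henry_vant_hoff van 't Hoff temperature-dependence parameter, K.
#'   Set to 0 to use `henry_constant` at all temperatures.
#' @return An object of class `lab_conditions`.
#' @export
lab_conditions <- function(temperature = 294.15, pressure = 1,
                           gas_constant = 0.082057,
                           henry_constant = 1.4e-3,
                           henry_ref_temperature = 298.15,
                           henry_vant_hoff = 1700) {
  stop_if_not_scalar_number(temperature, "temperature", positive = TRUE)
  stop_if_not_scalar_number(pressure, "pressure", positive = TRUE)
  stop_if_not_scalar_number(gas_constant, "gas_constant", positive = TRUE)
  stop_if_not_scalar_number(henry_constant, "henry_constant", positive = TRUE)
  stop_if_not_scalar_number(henry_ref_temperature, "henry_ref_temperature",
                            positive = TRUE)
  stop_if_not_scalar_number(henry_vant_hoff, "henry_vant_hoff")
  structure(list(temperature = temperature, pressure = pressure,
                 gas_constant = gas_constant, henry_constant = henry_constant,
                 henry_ref_temperature = henry_ref_temperature,
                 henry_vant_hoff = henry_vant_hoff),
            class = "lab_conditions")
}

#' Henry constant at the equilibration temperature
#'
#' van 't Hoff correction of the reference Henry solubility:
#' `K_H(T) = K_ref * exp(B * (1/T - 1/T_ref))`.
#'
#' @param lab A [lab_conditions()] object.
#' @return Henry constant at `lab$temperature`, mol L^-1 atm^-1.
#' @export
henry_at <- function(lab) {
  stopifnot(inherits(lab, "lab_conditions"))
  lab$henry_constant *
    exp(lab$henry_vant_hoff * (1 / lab$temperature - 1 / lab$henry_ref_temperature))
}

#' Moles of methane in the jar headspace
#'
#' Ideal-gas moles of CH4 in the headspace at equilibrium:
#' `n = (ppm * 1e-6) * P * V_hs / (R * T)`, linear in the mixing ratio.
#'
#' @param ppm CH4 mixing ratio in the headspace, ppm by volume (may be a
#'   vector).
#' @param geometry A [jar_geometry()] object.
#' @param lab A [lab_conditions()] object.
#' @return Moles of CH4 in the headspace (same length as `ppm`).
#' @export
headspace_moles <- function(ppm, geometry = jar_geometry(),
                            lab = lab_conditions()) {
  stopifnot(inherits(geometry, "jar_geometry"), inherits(lab, "lab_conditions"))
  if (any(!is.finite(ppm)) || any(ppm < 0))
    stop("`ppm` must be finite and >= 0", call. = FALSE)
  v_hs_l <- geometry$headspace_volume / 1000
  (ppm * 1e-6) * lab$pressure * v_hs_l / (lab$gas_constant * lab$temperature)
}

#' Moles of methane remaining dissolved in the jar's aqueous phase
#'
#' Henry's-law moles of CH4 dissolved at equilibrium in the aqueous phase,
#' which comprises the added water plus the sediment porewater
#' (`sediment_volume * porosity`): `n_aq = K_H(T) * p_CH4 * V_aq`.
#'
#' @inheritParams headspace_moles
#' @return Moles of dissolved CH4 (same length as `ppm`).
#' @export
dissolved_moles <- function(ppm, geometry = jar_geometry(),
                            lab = lab_conditions()) {
  stopifnot(inherits(geometry, "jar_geometry"), inherits(lab, "lab_conditions"))
  if (any(!is.finite(ppm)) || any(ppm < 0))
    stop("`ppm` must be finite and >= 0", call. = FALSE)
  v_aq_l <- (geometry$water_added +
               geometry$sediment_volume * geometry$porosity) / 1000
  partial_pressure <- (ppm * 1e-6) * lab$pressure
  henry_at(lab) * partial_pressure * v_aq_l
}

#' Total porewater methane from a headspace reading
#'
#' Headspace equilibration method: total CH4 in the jar (headspace plus, by
#' default, the fraction still dissolved in the aqueous phase at equilibrium)
#' is attributed to the original porewater volume
#' `sediment_volume * porosity` and expressed as a concentration in mM.
#'
#' @inheritParams headspace_moles
#' @param include_dissolved Include the Henry's-law dissolved fraction
#'   (default `TRUE`); `FALSE` counts headspace moles only.
#' @return Total porewater CH4 concentration, mM (same length as `ppm`).
#' @examples
#' total_porewater_methane(10000)  # 1 % CH4 in the default jar: ~0.82 mM
#' @export
total_porewater_methane <- function(ppm, geometry = jar_geometry(),
                                    lab = lab_conditions(),
                                    include_dissolved = TRUE) {
  stopifnot(inherits(geometry, "jar_geometry"))
  check_porosity(geometry$porosity)
  n <- headspace_moles(ppm, geometry, lab)
  if (include_dissolved)
    n <- n + dissolved_moles(ppm, geometry, lab)
  v_pw_l <- geometry$sediment_volume * geometry$porosity / 1000
  # mol / L = M; * 1000 -> mM
  1000 * n / v_pw_l
}

#' Headspace mixing ratio implied by a known porewater concentration
#'
#' Exact inverse of [total_porewater_methane()]: both the headspace and the
#' dissolved moles are linear in the mixing ratio, so the ppm reading that a
#' jar holding porewater of concentration `conc_mM` would produce is obtained
#' in closed form. Used by the synthetic-data generator; the round trip
#' `ppm_for_concentration` then `total_porewater_methane` is the identity.
#'
#' @param conc_mM True total porewater CH4 concentration, mM (vectorised).
#' @inheritParams total_porewater_methane
#' @return Headspace mixing ratio, ppm.
#' @export
ppm_for_concentration <- function(conc_mM, geometry = jar_geometry(),
                                  lab = lab_conditions(),
                                  include_dissolved = TRUE) {
  stopifnot(inherits(geometry, "jar_geometry"), inherits(lab, "lab_conditions"))
  if (any(!is.finite(conc_mM)) || any(conc_mM < 0))
    stop("`conc_mM` must be finite and >= 0", call. = FALSE)
  v_pw_l <- geometry$sediment_volume * geometry$porosity / 1000
  v_hs_l <- geometry$headspace_volume / 1000
  v_aq_l <- (geometry$water_added +
               geometry$sediment_volume * geometry$porosity) / 1000
  total_mol <- conc_mM * 1e-3 * v_pw_l
  per_ppm <- 1e-6 * lab$pressure *
    (v_hs_l / (lab$gas_constant * lab$temperature) +
       if (include_dissolved) henry_at(lab) * v_aq_l else 0)
  total_mol / per_ppm
}
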