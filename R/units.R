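# Unit conversions are centralized here so that no other file does ad-hoc
# arithmetic between mass and molar scales.  Working units: umol, umol/L, L,
# L/min, min.

#' Convert a dose in milligrams to micromoles
#'
#' @param mg dose in mg
#' @param molecular_weight g/mol
#' @return dose in umol
#' @export
mg_to_umol <- function(mg, molecular_weight) {
  stopifnot(molecular_weight > 0)
  mg / molecular_weight * 1000
}

#' Convert an amount in micromoles to milligrams
#'
#' @param umol amount in umol
#' @param molecular_weight g/mol
#' @return amount in mg
#' @export
umol_to_mg <- function(umol, molecular_weight) {
  stopifnot(molecular_weight > 0)
  umol * molecular_weight / 1000
}

#' Convert a molar concentration to a mass concentration
#'
#' umol/L x g/mol = ug/L; divided by 1000 gives ug/mL (= mg/L).
#'
#' @param umol_per_L concentration in umol/L
#' @param molecular_weight g/mol
#' @return concentration in ug/mL
#' @export
umolL_to_ugmL <- function(umol_per_L, molecular_weight) {
  umol_per_L * molecular_weight / 1000
}

#' Convert a mass concentration to a molar concentration
#'
#' @param ug_per_mL concentration in ug/mL
#' @param molecular_weight g/mol
#' @return concentration in umol/L
#' @export
ugmL_to_umolL <- function(ug_per_mL, molecular_weight) {
  ug_per_mL / molecular_weight * 1000
}

hours_to_minutes <- function(h) h * 60
minutes_to_hours <- function(min) min / 60
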