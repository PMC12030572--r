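#' Leaf nitrogen content (Kjeldahl titration)
#'
#' Total nitrogen in g per kg dry weight from a Kjeldahl determination:
#' `w1 = (V2 - V0) * c * 0.014 / (m * (V1 / V)) * 100`, where 0.014 g is the
#' nitrogen mass equivalent of 1 mL of 1 mol/L standard acid.
#'
#' @param c Acid standard concentration (mol/L), > 0.
#' @param V2 Titrant volume consumed by the sample (mL), >= `V0`.
#' @param V0 Titrant volume consumed by the blank (mL), >= 0.
#' @param V1 Distilled aliquot volume (mL), > 0 and <= `V`.
#' @param V Total test-solution volume (mL), > 0.
#' @param m Dry sample mass (g), > 0.
#' @return Nitrogen content in g/kg dry weight.
#' @export
nitrogen_content <- function(c, V2, V0, V1, V, m) {
  stopifnot(c > 0, V > 0, V1 > 0, V1 <= V, m > 0, V0 >= 0, V2 >= V0)
  (V2 - V0) * c * 0.014 / (m * (V1 / V)) * 100
}

#' Leaf phosphorus content (molybdenum-antimony colorimetry)
#'
#' `w2 = rho * (V / m) * (V2 / V1) * 1e-4`, in g per kg dry weight.
#'
#' @param rho Phosphorus mass concentration in the test solution (mg/L),
#'   >= 0.
#' @param V Total test-solution volume (mL), > 0.
#' @param V1 Dispensed aliquot volume (mL), > 0.
#' @param V2 Colour-solution volume (mL), > 0.
#' @param m Dry sample mass (g), > 0.
#' @return Phosphorus content in g/kg dry weight.
#' @export
phosphorus_content <- function(rho, V, V1, V2, m) {
  stopifnot(rho >= 0, V > 0, V1 > 0, V2 > 0, m > 0)
  rho * (V / m) * (V2 / V1) * 1e-4
}

#' Leaf potassium content (flame photometry)
#'
#' `w3 = (rho - rho0) * (V / m) * (V2 / V1) * 1e-4`, in g per kg dry weight;
#' the blank concentration `rho0` is subtracted before scaling, by parallel
#' with the phosphorus formula (so `potassium_content(rho, rho0 = 0, ...)`
#' equals `phosphorus_content(rho, ...)`).
#'
#' @param rho Potassium mass concentration in the test solution (mg/L).
#' @param rho0 Potassium concentration of the reagent blank (mg/L),
#'   `0 <= rho0 <= rho`.
#' @inheritParams phosphorus_content
#' @return Potassium content in g/kg dry weight.
#' @export
potassium_content <- function(rho, rho0, V, V1, V2, m) {
  stopifnot(rho >= 0, rho0 >= 0, rho >= rho0, V > 0, V1 > 0, V2 > 0, m > 0)
  (rho - rho0) * (V / m) * (V2 / V1) * 1e-4
}
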