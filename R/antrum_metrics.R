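## Quantitative antrum metrics: ellipse CSA and the Perlas volume model.

#' Antral cross-sectional area from two perpendicular diameters
#'
#' The antrum is modelled as an ellipse whose axes are the anteroposterior
#' and craniocaudal diameters measured serosa-to-serosa on the sagittal
#' epigastric view. Diameters are taken in millimetres (as usually reported)
#' and converted to centimetres internally, so the area comes out in cm^2:
#' `CSA = (d1/10) * (d2/10) * pi/4`.
#'
#' @param d1_mm anteroposterior diameter, mm.
#' @param d2_mm craniocaudal diameter, mm. Vectorized; the two arguments are
#'   interchangeable.
#' @return Cross-sectional area in cm^2.
#' @examples
#' csa_from_diameters(20, 20) # circle of diameter 2 cm: pi cm^2
#' @export
csa_from_diameters <- function(d1_mm, d2_mm) {
  d1_mm <- as.numeric(d1_mm)
  d2_mm <- as.numeric(d2_mm)
  if (any(!is.finite(d1_mm)) || any(!is.finite(d2_mm)) ||
      any(d1_mm < 0) || any(d2_mm < 0)) {
    gus_domain_error("diameters must be finite and non-negative (mm)")
  }
  (d1_mm / 10) * (d2_mm / 10) * pi / 4
}

#' Predicted gastric volume from RLD antral CSA and age
#'
#' Perlas' linear model for total gastric fluid volume:
#' `volume (mL) = 27.0 + 14.6 * CSA_RLD - 1.28 * age`, with CSA measured in
#' the right lateral decubitus (RLD) position in cm^2 and age in years. The
#' model can return negative values for small antra in elderly patients;
#' since a gastric volume cannot be negative, such predictions are clamped to
#' 0 mL and flagged. Supine CSA is never an implicit substitute: callers must
#' pass the RLD value.
#'
#' @param csa_rld_cm2 antral CSA in RLD, cm^2.
#' @param age age in years.
#' @param weight_kg optional body weight, kg; when given, the per-kg volume
#'   used by the aspiration-risk threshold is included.
#' @return A data.frame with columns `volume_ml`, `volume_ml_per_kg`
#'   (`NA` when weight is unknown) and `clamped`.
#' @examples
#' predicted_gastric_volume(5, 50, weight_kg = 72) # 36 mL, 0.5 mL/kg
#' @export
predicted_gastric_volume <- function(csa_rld_cm2, age, weight_kg = NULL) {
  csa_rld_cm2 <- as.numeric(csa_rld_cm2)
  age <- as.numeric(age)
  if (any(!is.finite(csa_rld_cm2)) || any(csa_rld_cm2 < 0)) {
    gus_domain_error("csa_rld_cm2 must be finite and non-negative")
  }
  if (any(!is.finite(age)) || any(age < 0)) {
    gus_domain_error("age must be finite and non-negative")
  }
  raw <- 27.0 + 14.6 * csa_rld_cm2 - 1.28 * age
  volume_ml <- pmax(raw, 0)
  per_kg <- if (is.null(weight_kg)) rep(NA_real_, length(volume_ml))
            else volume_per_kg(volume_ml, weight_kg)
  data.frame(volume_ml = volume_ml,
             volume_ml_per_kg = per_kg,
             clamped = raw < 0)
}

#' Weight-normalized gastric volume
#'
#' The aspiration-risk flowchart thresholds predicted volume at 1.5 mL per
#' kg of body weight, so the absolute prediction must be normalized by a
#' known positive weight.
#'
#' @param volume_ml predicted gastric volume, mL.
#' @param weight_kg body weight, kg; must be present and positive, otherwise
#'   the volume branch of the risk rule cannot be evaluated and a domain
#'   error is raised.
#' @return Volume in mL/kg.
#' @export
volume_per_kg <- function(volume_ml, weight_kg) {
  volume_ml <- as.numeric(volume_ml)
  weight_kg <- as.numeric(weight_kg)
  if (any(is.na(weight_kg)) || any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    gus_domain_error("weight_kg must be present and positive to normalize gastric volume")
  }
  if (any(!is.finite(volume_ml)) || any(volume_ml < 0)) {
    gus_domain_error("volume_ml must be finite and non-negative")
  }
  volume_ml / weight_kg
}
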