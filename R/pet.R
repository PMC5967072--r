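# PET quantification: SUV normalized to lean body mass, and blood-normalized
# tissue-to-background ratio (TBR).

#' Lean body mass
#'
#' James formula (default): male `1.10 W - 128 (W/H)^2`, female
#' `1.07 W - 148 (W/H)^2` with weight W in kg and height H in cm.  The
#' Janmahasatian formula is available as an alternative
#' (`9270 W / (6680 + 216 BMI)` male, `9270 W / (8780 + 244 BMI)` female,
#' BMI in kg/m^2).  Scanner vendors differ in which formula their SUV-LBM
#' implements; the choice here is a declared package decision.
#'
#' @param weight body weight (kg).
#' @param height body height (cm).
#' @param sex `"male"` or `"female"`.
#' @param method `"james"` (default) or `"janmahasatian"`.
#' @return Lean body mass (kg).  Errors if the result is non-positive
#'   (biometrics outside the formula's validity).
#' @export
lean_body_mass <- function(weight, height, sex = c("male", "female"),
                           method = c("james", "janmahasatian")) {
  sex <- match.arg(sex)
  method <- match.arg(method)
  chk_num(weight, "weight", lo = 0, open = TRUE, hi = 500)
  chk_num(height, "height", lo = 50, hi = 300)
  lbm <- switch(method,
    james = if (sex == "male") 1.10 * weight - 128 * (weight / height)^2
            else 1.07 * weight - 148 * (weight / height)^2,
    janmahasatian = {
      bmi <- weight / (height / 100)^2
      if (sex == "male") 9270 * weight / (6680 + 216 * bmi)
      else 9270 * weight / (8780 + 244 * bmi)
    })
  if (!is.finite(lbm) || lbm <= 0)
    user_stopf("lean body mass is non-positive for weight %.1f kg, height %.0f cm", weight, height)
  lbm
}

#' Radioactive decay factor
#'
#' @param t elapsed time (min) from injection to scan start.
#' @param half_life isotope half-life (min); default F-18 (109.77 min).
#' @return `exp(-ln 2 * t / half_life)`.
#' @export
decay_factor <- function(t, half_life = 109.77) {
  chk_num(t, "t", lo = 0)
  chk_num(half_life, "half_life", lo = 0, open = TRUE, hi = Inf)
  exp(-log(2) * t / half_life)
}

#' PET dose and biometric information
#'
#' @param injected_dose injected activity (MBq).
#' @param uptake_min minutes from injection to scan start (the dose is decay
#'   corrected to scan start).
#' @param weight,height,sex patient biometrics for [lean_body_mass()].
#' @param half_life isotope half-life (min), default F-18.
#' @param lbm_method LBM formula, see [lean_body_mass()].
#' @return An object of class `pet_dose_info`.
#' @export
pet_dose_info <- function(injected_dose, uptake_min, weight, height,
                          sex = "male", half_life = 109.77,
                          lbm_method = "james") {
  chk_num(injected_dose, "injected_dose", lo = 0, open = TRUE, hi = Inf)
  chk_num(uptake_min, "uptake_min", lo = 0)
  structure(list(injected_dose = injected_dose, uptake_min = uptake_min,
                 weight = weight, height = height, sex = sex,
                 half_life = half_life, lbm_method = lbm_method),
            class = "pet_dose_info")
}

# decay-corrected dose per lean body mass, the SUV-LBM denominator (MBq/kg)
.suv_denominator <- function(dose) {
  lbm <- lean_body_mass(dose$weight, dose$height, dose$sex, dose$lbm_method)
  dose$injected_dose * decay_factor(dose$uptake_min, dose$half_life) / lbm
}

#' Standardized uptake value normalized to lean body mass
#'
#' `SUV = activity / (decay-corrected dose / LBM)`, with activity in kBq/ml,
#' dose in MBq decay-corrected to scan start and LBM in kg (1 MBq/kg of
#' lean mass corresponds to 1 kBq/ml at unit tissue density).
#'
#' @param activity activity concentration (kBq/ml); vector or matrix.
#' @param dose a [pet_dose_info()].
#' @return SUV-LBM, same shape as `activity`.
#' @export
suv_lbm <- function(activity, dose) {
  if (any(activity < 0, na.rm = TRUE)) user_stopf("activity must be >= 0")
  activity / .suv_denominator(dose)
}

#' Convert a PET activity map to an SUV-LBM map
#'
#' @param activity_map a [scalar_map()] of activity (kBq/ml).
#' @param dose a [pet_dose_info()].
#' @return A [scalar_map()] of SUV-LBM.
#' @export
suv_map <- function(activity_map, dose) {
  v <- activity_map$data / .suv_denominator(dose)
  scalar_map(v, activity_map$mask, quantity = "suv", units = "SUV-LBM")
}

#' Tissue-to-background ratio
#'
#' Tissue signal divided by the blood-pool signal from an LV-centric region
#' of interest.  When a map and an ROI are given the blood statistic is the
#' ROI median.
#'
#' @param tissue tissue SUV (scalar, vector or matrix).
#' @param blood blood-pool SUV: either a positive scalar, or a
#'   [scalar_map()] combined with `roi`.
#' @param roi logical matrix selecting blood ROI pixels when `blood` is a
#'   map.
#' @return TBR, same shape as `tissue`.
#' @export
tbr <- function(tissue, blood, roi = NULL) {
  if (inherits(blood, "scalar_map")) {
    if (is.null(roi)) user_stopf("`roi` is required when `blood` is a map")
    v <- blood$data[roi]
    v <- v[is.finite(v)]
    if (!length(v)) user_stopf("blood ROI contains no finite values")
    blood <- stats::median(v)
  }
  chk_num(blood, "blood", lo = 0, open = TRUE, hi = Inf)
  tissue / blood
}
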