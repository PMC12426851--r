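#' Estimated glomerular filtration rate (MDRD)
#'
#' `eGFR = 175 * Cr^-1.154 * age^-0.203 * 1.212[black] * 0.742[female]`,
#' in mL/min/1.73 m^2, with serum creatinine in mg/dL.
#'
#' @param creatinine Serum creatinine (mg/dL), positive.
#' @param age Age in years, positive.
#' @param sex `"male"` or `"female"` (vectorized).
#' @param race_black Logical.
#' @return eGFR, vectorized over the inputs.
#' @export
egfr_mdrd <- function(creatinine, age, sex, race_black = FALSE) {
  if (any(creatinine <= 0) || any(age <= 0))
    stop("creatinine and age must be positive")
  sex <- match_sex(sex)
  175 * creatinine^-1.154 * age^-0.203 *
    ifelse(race_black, 1.212, 1) * ifelse(sex == "female", 0.742, 1)
}

match_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  sex
}

#' Left ventricular mass (Devereux) and its index
#'
#' `LVM = 0.8 * 1.04 * ((LVEDD + IVSd + PWd)^3 - LVEDD^3) + 0.6` grams, with
#' all linear dimensions in cm; the index divides by body surface area.
#'
#' @param lvedd LV end-diastolic diameter (cm).
#' @param ivsd Interventricular septal thickness in diastole (cm).
#' @param pwd Posterior wall thickness in diastole (cm).
#' @return LVM in grams.
#' @export
lvm_devereux <- function(lvedd, ivsd, pwd) {
  if (any(lvedd <= 0) || any(ivsd < 0) || any(pwd < 0))
    stop("echo dimensions must be positive")
  0.8 * 1.04 * ((lvedd + ivsd + pwd)^3 - lvedd^3) + 0.6
}

#' @rdname lvm_devereux
#' @param lvm Left ventricular mass (g).
#' @param bsa Body surface area (m^2), positive.
#' @return `lvm_index`: LVM / BSA in g/m^2.
#' @export
lvm_index <- function(lvm, bsa) {
  if (any(bsa <= 0)) stop("body surface area must be positive")
  lvm / bsa
}

required_fields <- function(baseline, fields, score) {
  miss <- fields[!fields %in% names(baseline)]
  if (length(miss))
    stop("scoring error (", score, "): missing field(s) ",
         paste(miss, collapse = ", "))
  for (f in fields) if (anyNA(baseline[[f]]))
    stop("scoring error (", score, "): NA in field ", f)
  invisible(TRUE)
}

#' CHA2DS2-VASc stroke risk score
#'
#' Congestive heart failure 1, hypertension 1, age >= 75 2, diabetes 1,
#' prior stroke/TIA 2, vascular disease 1, age 65-74 1, female sex 1
#' (age categories mutually exclusive; range 0-9). Vascular disease here is
#' coronary artery disease OR peripheral arterial occlusive disease, the
#' package's configurable mapping of EHR fields to that component.
#'
#' @param baseline data.frame with columns `age`, `sex`, `heart_failure`,
#'   `hypertension`, `diabetes`, `prior_stroke_tia`, `vascular_disease`.
#' @return Integer scores 0-9.
#' @export
cha2ds2_vasc <- function(baseline) {
  required_fields(baseline, c("age", "sex", "heart_failure", "hypertension",
                              "diabetes", "prior_stroke_tia",
                              "vascular_disease"), "CHA2DS2-VASc")
  sex <- match_sex(baseline$sex)
  age_pts <- ifelse(baseline$age >= 75, 2L, ifelse(baseline$age >= 65, 1L, 0L))
  as.integer(age_pts +
    (baseline$heart_failure > 0) + (baseline$hypertension > 0) +
    (baseline$diabetes > 0) + 2L * (baseline$prior_stroke_tia > 0) +
    (baseline$vascular_disease > 0) + (sex == "female"))
}

#' ATRIA stroke risk score
#'
#' Age points depend on prior-stroke status (without prior stroke: >= 85 -> 6,
#' 75-84 -> 5, 65-74 -> 3, < 65 -> 0; with prior stroke: >= 85 -> 9,
#' 75-84 -> 7, 65-74 -> 7, < 65 -> 8), plus 1 point each for female sex,
#' diabetes, congestive heart failure, hypertension, proteinuria, and
#' eGFR < 45 or end-stage renal disease; range 0-15. If `egfr` is absent it
#' is derived from creatinine, age, sex and race via [egfr_mdrd()].
#'
#' @param baseline data.frame with columns `age`, `sex`, `prior_stroke_tia`,
#'   `diabetes`, `heart_failure`, `hypertension`, `proteinuria`, `esrd`, and
#'   `egfr` or `creatinine` (+ optional `race_black`).
#' @return Integer scores 0-15.
#' @export
atria_score <- function(baseline) {
  required_fields(baseline, c("age", "sex", "prior_stroke_tia", "diabetes",
                              "heart_failure", "hypertension", "proteinuria",
                              "esrd"), "ATRIA")
  if (is.null(baseline$egfr)) {
    required_fields(baseline, "creatinine", "ATRIA")
    baseline$egfr <- egfr_mdrd(baseline$creatinine, baseline$age,
                               baseline$sex, baseline$race_black %||% FALSE)
  }
  sex <- match_sex(baseline$sex)
  stroke <- baseline$prior_stroke_tia > 0
  age <- baseline$age
  age_pts <- ifelse(stroke,
                    ifelse(age >= 85, 9L, ifelse(age >= 75, 7L,
                           ifelse(age >= 65, 7L, 8L))),
                    ifelse(age >= 85, 6L, ifelse(age >= 75, 5L,
                           ifelse(age >= 65, 3L, 0L))))
  as.integer(age_pts + (sex == "female") + (baseline$diabetes > 0) +
    (baseline$heart_failure > 0) + (baseline$hypertension > 0) +
    (baseline$proteinuria > 0) +
    (baseline$egfr < 45 | baseline$esrd > 0))
}
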