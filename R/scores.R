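# Clinical point scores predicting post-thrombolysis hemorrhagic
# transformation (HT) and functional outcome from on-admission data. All
# calculators are vectorized and validate their physiologic ranges.

.check_range <- function(x, lo, hi, name) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad))
    stop("'", name, "' out of range at position ", bad[1],
         " (value ", x[bad[1]], ", allowed ", lo, "-", hi, ")")
  invisible(x)
}

#' DRAGON score
#'
#' Additive 0-10 score predicting functional outcome after intravenous
#' thrombolysis. Components: HMCA sign / ASPECTS < 10 (both = 2, either = 1,
#' none = 0); pre-stroke mRS > 1 (1 point); age (>= 80 years = 2, 65-79 = 1,
#' < 65 = 0, non-integer ages floored); glucose > 8 mmol/L (1 point);
#' onset-to-treatment time strictly > 90 min (1 point); NIHSS (> 15 = 3,
#' 10-15 = 2, 5-9 = 1, 0-4 = 0).
#'
#' @param hmca Hyperdense middle-cerebral-artery sign (0/1).
#' @param aspects ASPECTS, integer 0-10.
#' @param prestroke_mrs Pre-stroke modified Rankin Scale, integer 0-6.
#' @param age Age in years.
#' @param glucose Admission glucose, mmol/L.
#' @param onset_to_treatment Onset-to-treatment time, minutes.
#' @param nihss NIHSS, integer 0-42.
#' @return Integer score(s) in 0-10.
#' @export
compute_dragon <- function(hmca, aspects, prestroke_mrs, age, glucose,
                           onset_to_treatment, nihss) {
  .check_range(hmca, 0, 1, "hmca")
  .check_range(aspects, 0, 10, "aspects")
  .check_range(prestroke_mrs, 0, 6, "prestroke_mrs")
  .check_range(age, 0, 120, "age")
  .check_range(glucose, 0.5, 60, "glucose")
  .check_range(onset_to_treatment, 0, 1440, "onset_to_treatment")
  .check_range(nihss, 0, 42, "nihss")
  age <- floor(age)
  hd <- (hmca == 1) + (aspects < 10)
  as.integer(
    hd +
      (prestroke_mrs > 1) +
      ifelse(age >= 80, 2L, ifelse(age >= 65, 1L, 0L)) +
      (glucose > 8) +
      (onset_to_treatment > 90) +
      ifelse(nihss > 15, 3L, ifelse(nihss >= 10, 2L, ifelse(nihss >= 5, 1L, 0L)))
  )
}

#' SEDAN score
#'
#' Additive 0-6 score for symptomatic HT risk after thrombolysis.
#' Components: glucose (8.1-12.0 mmol/L = 1, > 12.0 = 2, implemented as
#' (8.0, 12.0] and (12.0, Inf) on the measured value); ASPECTS < 10
#' (1 point); HMCA sign (1 point); age > 75 years (1 point); NIHSS >= 10
#' (1 point).
#'
#' @inheritParams compute_dragon
#' @return Integer score(s) in 0-6.
#' @export
compute_sedan <- function(glucose, aspects, hmca, age, nihss) {
  .check_range(glucose, 0.5, 60, "glucose")
  .check_range(aspects, 0, 10, "aspects")
  .check_range(hmca, 0, 1, "hmca")
  .check_range(age, 0, 120, "age")
  .check_range(nihss, 0, 42, "nihss")
  as.integer(
    ifelse(glucose > 12, 2L, ifelse(glucose > 8, 1L, 0L)) +
      (aspects < 10) +
      (hmca == 1) +
      (age > 75) +
      (nihss >= 10)
  )
}

#' HTI score
#'
#' Additive 0-8 Hemorrhagic Transformation Index for middle-cerebral-artery
#' stroke. Components: ASPECTS (10-7 = 0, 6-5 = 1, 4-3 = 2, 2-0 = 3); NIHSS
#' (0-11 = 0, 12-17 = 1, 18-23 = 2, > 23 = 3); HMCA sign (1 point); atrial
#' fibrillation on ECG (1 point).
#'
#' @inheritParams compute_dragon
#' @param af_ecg Atrial fibrillation on the admission ECG (0/1).
#' @return Integer score(s) in 0-8.
#' @export
compute_hti <- function(aspects, nihss, hmca, af_ecg) {
  .check_range(aspects, 0, 10, "aspects")
  .check_range(nihss, 0, 42, "nihss")
  .check_range(hmca, 0, 1, "hmca")
  .check_range(af_ecg, 0, 1, "af_ecg")
  as.integer(
    ifelse(aspects >= 7, 0L, ifelse(aspects >= 5, 1L, ifelse(aspects >= 3, 2L, 3L))) +
      ifelse(nihss > 23, 3L, ifelse(nihss >= 18, 2L, ifelse(nihss >= 12, 1L, 0L))) +
      (hmca == 1) +
      (af_ecg == 1)
  )
}

#' Grade hemorrhagic-transformation risk from the HTI score
#'
#' Collapses the HTI score into the three-level risk grade used for
#' subgroup reporting: low (HTI = 0), moderate (HTI = 1), high (HTI >= 2).
#'
#' @param hti Integer HTI score(s) in 0-8.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
grade_ht_risk <- function(hti) {
  .check_range(hti, 0, 8, "hti")
  factor(ifelse(hti >= 2, "high", ifelse(hti == 1, "moderate", "low")),
         levels = c("low", "moderate", "high"))
}

#' Attach score columns to a cohort
#'
#' Computes DRAGON, SEDAN and HTI (plus the HT risk grade) from the
#' on-admission covariates of a [cohort_schema()] table and appends them as
#' columns `dragon`, `sedan`, `hti`, `grade`.
#'
#' @param cohort Patient-level data frame.
#' @param scores Which scores to add.
#' @return The cohort with score columns appended.
#' @export
add_scores <- function(cohort, scores = c("dragon", "sedan", "hti")) {
  scores <- match.arg(scores, several.ok = TRUE)
  if ("dragon" %in% scores)
    cohort$dragon <- compute_dragon(cohort$hmca, cohort$aspects,
                                    cohort$prestroke_mrs, cohort$age,
                                    cohort$glucose, cohort$onset_to_treatment,
                                    cohort$nihss)
  if ("sedan" %in% scores)
    cohort$sedan <- compute_sedan(cohort$glucose, cohort$aspects, cohort$hmca,
                                  cohort$age, cohort$nihss)
  if ("hti" %in% scores) {
    cohort$hti <- compute_hti(cohort$aspects, cohort$nihss, cohort$hmca,
                              cohort$af_ecg)
    cohort$grade <- grade_ht_risk(cohort$hti)
  }
  cohort
}
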