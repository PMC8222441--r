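#' Pediatric Assessment Triangle (PAT)
#'
#' The PAT is the rapid visual first look at a child: general appearance,
#' work of breathing, and circulation to the skin. Each arm is recorded as
#' `"normal"`, `"abnormal"` or `"not_assessed"`; the triangle is abnormal
#' when at least one arm is abnormal.
#'
#' @param appearance,work_of_breathing,circulation One of `"normal"`,
#'   `"abnormal"`, `"not_assessed"`.
#' @return A `pat_assessment` object.
#' @export
pat_assessment <- function(appearance = "normal",
                           work_of_breathing = "normal",
                           circulation = "normal") {
  states <- c("normal", "abnormal", "not_assessed")
  arms <- list(appearance = appearance,
               work_of_breathing = work_of_breathing,
               circulation = circulation)
  for (nm in names(arms)) {
    if (!(is.character(arms[[nm]]) && length(arms[[nm]]) == 1 &&
          arms[[nm]] %in% states)) {
      stop("PAT arm '", nm, "' must be one of ",
           paste(states, collapse = ", "), call. = FALSE)
    }
  }
  structure(arms, class = "pat_assessment")
}

#' @rdname pat_assessment
#' @param pat A `pat_assessment` object.
#' @export
pat_is_abnormal <- function(pat) {
  stopifnot(inherits(pat, "pat_assessment"))
  any(unlist(pat) == "abnormal")
}

#' Recorded vital signs
#'
#' Missingness is explicit: an unrecorded vital is `NA`, never 0.
#'
#' @param temperature Body temperature, deg C, or `NA`.
#' @param heart_rate Heart rate, beats/min, or `NA`.
#' @param respiratory_rate Respiratory rate, breaths/min, or `NA`.
#' @param systolic_bp Systolic blood pressure, mmHg, or `NA`.
#' @param spo2 Oxygen saturation, percent (0-100], or `NA`.
#' @return A `vital_signs` object (named list of scalars).
#' @export
vital_signs <- function(temperature = NA_real_, heart_rate = NA_real_,
                        respiratory_rate = NA_real_, systolic_bp = NA_real_,
                        spo2 = NA_real_) {
  v <- list(temperature = as.numeric(temperature),
            heart_rate = as.numeric(heart_rate),
            respiratory_rate = as.numeric(respiratory_rate),
            systolic_bp = as.numeric(systolic_bp),
            spo2 = as.numeric(spo2))
  for (nm in names(v)) {
    if (length(v[[nm]]) != 1) stop("vital '", nm, "' must be a scalar")
    if (!is.na(v[[nm]]) && v[[nm]] <= 0) {
      stop("vital '", nm, "' must be positive or NA, got ", v[[nm]],
           call. = FALSE)
    }
  }
  if (!is.na(v$spo2) && v$spo2 > 100) stop("spo2 must be <= 100", call. = FALSE)
  structure(v, class = "vital_signs")
}

#' Triage-time snapshot of a pediatric ED presentation
#'
#' Bundles everything the triage nurse has in hand when assigning a level:
#' the PAT, the recorded vitals, high-risk situation codes, whether an
#' immediate life-saving intervention is needed, and the predicted number of
#' ESI-sense resources. `predicted_resources` is the nurse's forward-looking
#' judgment and is deliberately distinct from the resources actually used,
#' which belong to the encounter outcome.
#'
#' @param age_months Age in months, `0 <= age < 180` (under 15 years).
#' @param pat A [pat_assessment()].
#' @param vitals A [vital_signs()].
#' @param chief_complaint Free-form complaint code (e.g. `"fever"`).
#' @param trauma Logical: trauma-related presentation.
#' @param needs_lifesaving_intervention Logical: an immediate airway /
#'   breathing / circulation intervention is required.
#' @param high_risk_flags Character vector of high-risk situation codes from
#'   the configured registry; `character(0)` when none.
#' @param accessory_muscle_use,wheezing_or_rhonchi,crying Logical
#'   observations recorded at triage.
#' @param full_consciousness,full_pulse Logical; `TRUE` is the normal state.
#' @param predicted_resources Non-negative integer count of anticipated
#'   resources.
#' @return A `patient_presentation` object.
#' @export
patient_presentation <- function(age_months,
                                 pat = pat_assessment(),
                                 vitals = vital_signs(),
                                 chief_complaint = "other",
                                 trauma = FALSE,
                                 needs_lifesaving_intervention = FALSE,
                                 high_risk_flags = character(0),
                                 accessory_muscle_use = FALSE,
                                 wheezing_or_rhonchi = FALSE,
                                 crying = FALSE,
                                 full_consciousness = TRUE,
                                 full_pulse = TRUE,
                                 predicted_resources = 0L) {
  age_months <- as.numeric(age_months)
  if (length(age_months) != 1 || is.na(age_months) ||
      age_months < 0 || age_months >= 180) {
    stop("age_months must be a scalar in [0, 180) (patients under 15 years)",
         call. = FALSE)
  }
  predicted_resources <- as.integer(predicted_resources)
  if (is.na(predicted_resources) || predicted_resources < 0) {
    stop("predicted_resources must be a non-negative integer", call. = FALSE)
  }
  stopifnot(inherits(pat, "pat_assessment"), inherits(vitals, "vital_signs"))
  structure(
    list(age_months = age_months, pat = pat, vitals = vitals,
         chief_complaint = as.character(chief_complaint),
         trauma = isTRUE(trauma),
         needs_lifesaving_intervention = isTRUE(needs_lifesaving_intervention),
         high_risk_flags = as.character(high_risk_flags),
         accessory_muscle_use = isTRUE(accessory_muscle_use),
         wheezing_or_rhonchi = isTRUE(wheezing_or_rhonchi),
         crying = isTRUE(crying),
         full_consciousness = isTRUE(full_consciousness),
         full_pulse = isTRUE(full_pulse),
         predicted_resources = predicted_resources),
    class = "patient_presentation"
  )
}

#' Encounter outcome
#'
#' What actually happened after the physician's evaluation: resources used
#' and final disposition. "Admitted" means disposition ward, ICU, or the
#' operating room from the ED. A death in the ED is counted with admissions
#' for screening purposes; an ED death with disposition `"discharge"` is
#' rejected as inconsistent.
#'
#' @param resources_used Non-negative integer.
#' @param disposition One of `"discharge"`, `"ward"`, `"icu"`, `"ed_or"`.
#' @param ed_death Logical.
#' @param resource_items Optional character vector of resource codes.
#' @return An `encounter_outcome` object.
#' @export
encounter_outcome <- function(resources_used, disposition,
                              ed_death = FALSE,
                              resource_items = character(0)) {
  resources_used <- as.integer(resources_used)
  if (is.na(resources_used) || resources_used < 0) {
    stop("resources_used must be a non-negative integer", call. = FALSE)
  }
  dispositions <- c("discharge", "ward", "icu", "ed_or")
  if (!(length(disposition) == 1 && disposition %in% dispositions)) {
    stop("disposition must be one of ", paste(dispositions, collapse = ", "),
         call. = FALSE)
  }
  if (isTRUE(ed_death) && disposition == "discharge") {
    stop("inconsistent outcome: ed_death with disposition 'discharge'",
         call. = FALSE)
  }
  structure(
    list(resources_used = resources_used,
         disposition = disposition,
         ed_death = isTRUE(ed_death),
         resource_items = as.character(resource_items)),
    class = "encounter_outcome"
  )
}

#' @rdname encounter_outcome
#' @param outcome An `encounter_outcome` object.
#' @export
outcome_admitted <- function(outcome) {
  stopifnot(inherits(outcome, "encounter_outcome"))
  outcome$disposition %in% c("ward", "icu", "ed_or")
}
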