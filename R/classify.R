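#' Classify a pediatric presentation into triage level 1-5
#'
#' Applies the five-level decision flow in strict priority order; the first
#' matching rule wins:
#'
#' 1. **Level 1** - abnormal PAT (any arm) or need for an immediate
#'    life-saving intervention. Seen immediately (time target 0 min).
#' 2. **Level 2** - any recorded vital sign outside its age-band reference
#'    range, or any high-risk situation code. Seen within 10 min. A single
#'    out-of-range vital suffices; this is the conservative reading when a
#'    protocol does not state a combination rule.
#' 3. **Level 3** - predicted need for two or more resources. Within 60 min.
#' 4. **Level 4** - predicted need for exactly one resource. No guaranteed
#'    waiting time (re-evaluated while waiting).
#' 5. **Level 5** - no resources predicted. No guaranteed waiting time.
#'
#' Missing vitals never escalate: the cohort this instrument targets has
#' unrecorded vitals (a few percent of saturations, for instance) and those
#' encounters are still classified. With `strict = TRUE` a presentation with
#' any unmeasured vital is flagged for re-triage in the rationale
#' (`"unmeasured_vitals"`) without changing the level.
#'
#' @param p A [patient_presentation()].
#' @param ref An `spt_config` (reference table + registries).
#' @param strict Logical; flag unmeasured vitals for re-triage.
#' @return A `triage_result`: list with `level` (integer 1-5), `rationale`
#'   (ordered character vector of fired rule identifiers) and
#'   `time_target_minutes` (0, 10, 60 or `NA` for "not guaranteed").
#' @examples
#' cfg <- spt_reference_table()
#' p <- patient_presentation(24, pat = pat_assessment(appearance = "abnormal"))
#' spt_classify(p, cfg)$level
#' @export
spt_classify <- function(p, ref = spt_reference_table(), strict = FALSE) {
  stopifnot(inherits(p, "patient_presentation"), inherits(ref, "spt_config"))

  rationale <- character(0)
  # level 1 gate: PAT arms in canonical order, then LSI
  if (p$pat$appearance == "abnormal")        rationale <- c(rationale, "pat_appearance_abnormal")
  if (p$pat$work_of_breathing == "abnormal") rationale <- c(rationale, "pat_breathing_abnormal")
  if (p$pat$circulation == "abnormal")       rationale <- c(rationale, "pat_circulation_abnormal")
  if (p$needs_lifesaving_intervention)       rationale <- c(rationale, "lifesaving_intervention")
  if (length(rationale) > 0) {
    return(new_triage_result(1L, rationale, strict, p))
  }

  # level 2 gate: vitals first (canonical vital order), then high-risk codes
  vflags <- vitals_abnormal(p$vitals, p$age_months, ref)
  hflags <- sort(unique(p$high_risk_flags))
  if (length(vflags) > 0 || length(hflags) > 0) {
    rationale <- c(paste0("vital_", vflags),
                   if (length(hflags)) paste0("high_risk_", hflags))
    return(new_triage_result(2L, rationale, strict, p))
  }

  # resource ladder
  if (p$predicted_resources >= 2L) {
    new_triage_result(3L, "resources_ge2", strict, p)
  } else if (p$predicted_resources == 1L) {
    new_triage_result(4L, "resources_eq1", strict, p)
  } else {
    new_triage_result(5L, "resources_eq0", strict, p)
  }
}

new_triage_result <- function(level, rationale, strict = FALSE, p = NULL) {
  if (strict && !is.null(p) && any(is.na(unlist(p$vitals)))) {
    rationale <- c(rationale, "unmeasured_vitals")
  }
  structure(
    list(level = level,
         rationale = rationale,
         time_target_minutes = level_time_target(level)),
    class = "triage_result"
  )
}

# Time-to-physician targets: level 1 immediately, 2 within 10 min, 3 within
# 60 min; levels 4-5 carry no guarantee (NA).
level_time_target <- function(level) {
  c(0, 10, 60, NA_real_, NA_real_)[level]
}

#' @export
print.triage_result <- function(x, ...) {
  tt <- if (is.na(x$time_target_minutes)) "not guaranteed"
        else paste0("<= ", x$time_target_minutes, " min")
  cat("Triage level ", x$level, " (time to physician: ", tt, ")\n", sep = "")
  cat("Fired rules:", paste(x$rationale, collapse = ", "), "\n")
  invisible(x)
}

#' Classify every encounter in a cohort table
#'
#' Vectorised wrapper around the level-assignment flow for a cohort data
#' frame (see [cohort_schema()] for the column dictionary). Appends `level`,
#' `rationale` (`";"`-joined fired rules) and `time_target_minutes` columns.
#'
#' @param cohort Data frame with presentation columns (`age_months`,
#'   `pat_appearance`, `pat_breathing`, `pat_circulation`, `lsi`,
#'   `high_risk`, the five vitals, `predicted_resources`).
#' @param ref An `spt_config`.
#' @return `cohort` with classification columns appended (existing `level`
#'   columns are overwritten).
#' @export
classify_cohort <- function(cohort, ref = spt_reference_table()) {
  stopifnot(is.data.frame(cohort), inherits(ref, "spt_config"))
  req <- c("age_months", "pat_appearance", "pat_breathing", "pat_circulation",
           "lsi", "high_risk", "predicted_resources")
  miss <- setdiff(req, names(cohort))
  if (length(miss) > 0) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(cohort)
  pat_ab <- (cohort$pat_appearance == "abnormal" |
             cohort$pat_breathing == "abnormal" |
             cohort$pat_circulation == "abnormal")
  lsi <- as.logical(cohort$lsi)
  vflags <- vitals_flags_cohort(cohort, ref)
  hflags <- strsplit(ifelse(is.na(cohort$high_risk), "", cohort$high_risk), ";",
                     fixed = TRUE)
  hflags <- lapply(hflags, function(x) sort(unique(x[nzchar(x)])))
  pres <- as.integer(cohort$predicted_resources)

  level <- integer(n)
  rationale <- character(n)
  for (i in seq_len(n)) {
    if (pat_ab[i] || lsi[i]) {
      level[i] <- 1L
      r <- character(0)
      if (cohort$pat_appearance[i] == "abnormal") r <- c(r, "pat_appearance_abnormal")
      if (cohort$pat_breathing[i] == "abnormal")  r <- c(r, "pat_breathing_abnormal")
      if (cohort$pat_circulation[i] == "abnormal") r <- c(r, "pat_circulation_abnormal")
      if (lsi[i]) r <- c(r, "lifesaving_intervention")
      rationale[i] <- paste(r, collapse = ";")
    } else if (length(vflags[[i]]) > 0 || length(hflags[[i]]) > 0) {
      level[i] <- 2L
      rationale[i] <- paste(
        c(paste0("vital_", vflags[[i]]),
          if (length(hflags[[i]])) paste0("high_risk_", hflags[[i]])),
        collapse = ";")
    } else if (pres[i] >= 2L) {
      level[i] <- 3L; rationale[i] <- "resources_ge2"
    } else if (pres[i] == 1L) {
      level[i] <- 4L; rationale[i] <- "resources_eq1"
    } else {
      level[i] <- 5L; rationale[i] <- "resources_eq0"
    }
  }
  cohort$level <- level
  cohort$rationale <- rationale
  cohort$time_target_minutes <- level_time_target(level)
  cohort
}
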