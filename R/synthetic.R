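#' Specification for a synthetic pediatric ED cohort
#'
#' Defines the margins a stochastic synthetic cohort is drawn from. The
#' defaults are calibrated to the validation study this package models: a
#' 520-encounter cohort with level weights 10/247/155/100/8, the per-level
#' resource-use and admission margins of its published cross-tabs, median
#' age 36 months (IQR 12-84), 53.7% boys, and ~4.6% missing oxygen
#' saturation.
#'
#' @param n Cohort size (ignored when `level_counts` is given).
#' @param level_weights Probability weights for levels 1-5.
#' @param level_counts Optional exact integer counts per level (length 5);
#'   overrides `n` and `level_weights`.
#' @param resource_probs 5x3 matrix of per-level probabilities of using
#'   `>=2`, `1`, `0` resources (rows = levels).
#' @param admission_prob Per-level probability of admission.
#' @param admit_split 5x3 matrix: given admission, probabilities of
#'   ICU / ward / ED-OR (rows = levels).
#' @param spo2_trigger_prob Probability that a level-2 encounter's gate is a
#'   desaturation (otherwise a high-risk code).
#' @param male_p Proportion male.
#' @param age_meanlog,age_sdlog Log-normal age distribution (months),
#'   truncated to `[0, 180)`.
#' @param spo2_missing_prob Missingness rate for oxygen saturation (never
#'   applied to encounters whose level-2 gate is the saturation itself).
#' @param complaint_probs Named probability vector over chief complaints.
#' @param consistency Fraction of rows whose presentation must be consistent
#'   with the sampled level (1 = every row survives a classification
#'   round-trip).
#' @param seed Default seed used by [generate_cohort()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n = 520,
                        level_weights = c(10, 247, 155, 100, 8) / 520,
                        level_counts = NULL,
                        resource_probs = rbind(
                          c(10, 0, 0) / 10,
                          c(156, 73, 18) / 247,
                          c(67, 66, 22) / 155,
                          c(10, 56, 34) / 100,
                          c(0, 2, 6) / 8),
                        admission_prob = c(1, 78 / 247, 26 / 155, 2 / 100, 0),
                        admit_split = rbind(
                          c(4, 6, 0) / 10,
                          c(3, 75, 0) / 78,
                          c(0, 24, 2) / 26,
                          c(0, 1, 0),
                          c(0, 1, 0)),
                        spo2_trigger_prob = 30 / 247,
                        male_p = 0.537,
                        age_meanlog = log(36), age_sdlog = 1.4,
                        spo2_missing_prob = 0.046,
                        complaint_probs = c(
                          fever = 199, dyspnea = 65, nausea_vomiting = 41,
                          abdominal_pain = 25, diarrhea = 16, seizure = 10,
                          altered_consciousness = 2, other = 162) / 520,
                        consistency = 1,
                        seed = 1L) {
  if (is.null(level_counts)) {
    if (!(is.numeric(n) && length(n) == 1 && n > 0)) {
      stop("spec error: n must be a positive scalar", call. = FALSE)
    }
  } else {
    if (length(level_counts) != 5 || any(level_counts < 0) ||
        sum(level_counts) == 0) {
      stop("spec error: level_counts must be 5 non-negative counts",
           call. = FALSE)
    }
    n <- sum(level_counts)
  }
  check_prob <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("spec error: ", what, " must be a probability vector summing to 1",
           call. = FALSE)
    }
  }
  check_prob(level_weights, "level_weights")
  for (i in 1:5) check_prob(resource_probs[i, ], paste0("resource_probs[", i, ",]"))
  if (any(admission_prob < 0 | admission_prob > 1)) {
    stop("spec error: admission_prob must lie in [0, 1]", call. = FALSE)
  }
  check_prob(complaint_probs, "complaint_probs")
  w1 <- if (is.null(level_counts)) level_weights[1] else level_counts[1]
  if (w1 > 0 && admission_prob[1] <= 0) {
    stop("spec error: level-1 weight with zero admission probability is ",
         "infeasible (level-1 encounters are admitted by definition of ",
         "appropriate triage)", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), level_weights = level_weights,
         level_counts = level_counts, resource_probs = resource_probs,
         admission_prob = admission_prob, admit_split = admit_split,
         spo2_trigger_prob = spo2_trigger_prob, male_p = male_p,
         age_meanlog = age_meanlog, age_sdlog = age_sdlog,
         spo2_missing_prob = spo2_missing_prob,
         complaint_probs = complaint_probs,
         consistency = consistency, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a stochastic synthetic cohort
#'
#' Draws `spec$n` encounters whose presentation is consistent with the
#' sampled triage level (a level-2 row carries a desaturation or a
#' high-risk code; levels 3-5 have in-range vitals and the matching
#' predicted resource count), and whose outcomes follow the per-level
#' resource and admission margins of the spec.
#'
#' Every sampled value is a deterministic function of
#' `(seed, encounter_id, field)` through a counter-based hash generator, so
#' the same seed reproduces the cohort exactly and row order never
#' influences sampled values.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param ref An `spt_config` used to place in-range vitals.
#' @return A cohort data frame in the standard column dictionary (see
#'   [cohort_schema()]), including assigned `level` and outcome columns.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 50), seed = 7)
#' table(cohort$level)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed,
                            ref = spt_reference_table()) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(seed)
  n <- spec$n
  id <- seq_len(n)
  u <- function(field) ctr_unif(seed, id, ctr_field(field))

  level <- if (is.null(spec$level_counts)) {
    ctr_sample(seed, id, ctr_field("level"), spec$level_weights, 1:5)
  } else {
    rep(1:5, times = spec$level_counts)
  }

  # outcomes: resources used and disposition follow per-level margins
  ures <- u("resources_used")
  res_cat <- integer(n)   # 1 = >=2, 2 = one, 3 = none
  for (l in 1:5) {
    sel <- level == l
    cdf <- cumsum(spec$resource_probs[l, ])
    res_cat[sel] <- findInterval(ures[sel], cdf, left.open = TRUE) + 1L
  }
  resources_used <- c(2L, 1L, 0L)[res_cat]
  admitted <- u("admitted") < spec$admission_prob[level]
  disposition <- rep("discharge", n)
  uadm <- u("admit_type")
  for (l in 1:5) {
    sel <- level == l & admitted
    if (!any(sel)) next
    cdf <- cumsum(spec$admit_split[l, ])
    disposition[sel] <- c("icu", "ward", "ed_or")[
      findInterval(uadm[sel], cdf, left.open = TRUE) + 1L]
  }

  # demographics
  sex <- ifelse(u("sex") < spec$male_p, "male", "female")
  pmax_age <- stats::plnorm(180, spec$age_meanlog, spec$age_sdlog)
  age_months <- pmin(179L, as.integer(floor(stats::qlnorm(
    u("age") * pmax_age, spec$age_meanlog, spec$age_sdlog))))

  # presentation consistent with level
  consistent <- u("predicted_extra") < spec$consistency
  pat_appearance <- rep("normal", n)
  pat_breathing <- rep("normal", n)
  pat_circulation <- rep("normal", n)
  is1 <- level == 1L
  arm <- ctr_sample(seed, id, ctr_field("trigger"), c(0.6, 0.4),
                    c("appearance", "breathing"))
  pat_appearance[is1 & arm == "appearance"] <- "abnormal"
  pat_breathing[is1 & arm == "breathing"] <- "abnormal"

  spo2_gate <- level == 2L & u("trigger") < spec$spo2_trigger_prob
  high_risk <- rep("", n)
  high_risk[level == 2L & !spo2_gate & consistent] <- "hr_sepsis_warning"
  spo2_gate <- spo2_gate & consistent

  # vitals: in-range values drawn within the middle of the age band
  tab <- ref$reference_table
  bi <- band_index(age_months, ref)
  mid <- function(abbr, uu) {
    lo <- tab[[paste0(abbr, "_low")]][bi]
    hi <- tab[[paste0(abbr, "_high")]][bi]
    lo + (0.25 + 0.5 * uu) * (hi - lo)
  }
  temperature <- round(mid("temp", u("temp_jitter")), 1)
  heart_rate <- round(mid("hr", u("hr_jitter")))
  respiratory_rate <- round(mid("rr", u("rr_jitter")))
  systolic_bp <- round(mid("sbp", u("sbp_jitter")))
  spo2 <- rep(98, n)
  spo2[spo2_gate] <- 92
  spo2_missing <- !spo2_gate & u("spo2_missing") < spec$spo2_missing_prob
  spo2[spo2_missing] <- NA_real_

  # risk/observation factors: marginal prevalences from the calibration
  underlying <- u("underlying") < 122 / 520
  underlying_resp <- underlying & (u("underlying_resp") < 55 / 122)
  chief_complaint <- ctr_sample(seed, id, ctr_field("chief_complaint"),
                                spec$complaint_probs,
                                names(spec$complaint_probs))
  predicted_resources <- c(3L, 2L, 2L, 1L, 0L)[level]

  out <- data.frame(
    encounter_id = id,
    age_months = age_months,
    sex = sex,
    pat_appearance = pat_appearance,
    pat_breathing = pat_breathing,
    pat_circulation = pat_circulation,
    lsi = FALSE,
    high_risk = high_risk,
    temperature = temperature,
    heart_rate = heart_rate,
    respiratory_rate = respiratory_rate,
    systolic_bp = systolic_bp,
    spo2 = spo2,
    chief_complaint = chief_complaint,
    trauma = u("trauma") < 95 / 520,
    underlying_disease = underlying,
    underlying_resp_disease = underlying_resp,
    accessory_muscle_use = u("accessory") < 26 / 520,
    wheezing_rhonchi = u("wheezing") < 92 / 520,
    crying = u("crying") < 66 / 520,
    full_pulse = TRUE,
    full_consciousness = TRUE,
    predicted_resources = predicted_resources,
    level = level,
    resources_used = resources_used,
    disposition = disposition,
    ed_death = FALSE,
    retro_pat_abnormal = FALSE,
    retro_lsi = FALSE,
    retro_vitals_abnormal = FALSE,
    retro_high_risk = FALSE,
    work_shift = ctr_sample(seed, id, ctr_field("shift"),
                            c(128, 288, 104) / 520,
                            c("morning", "evening", "night")),
    workday = u("workday") < 0.546,
    self_transport = u("self_transport") < 0.958,
    nurse_experience_gt10y = u("nurse_exp") < 328 / 520,
    overcrowded = u("overcrowded") < 307 / 520,
    stringsAsFactors = FALSE
  )
  out
}
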