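#' Adjudicate a triaged encounter as appropriate, over- or under-triaged
#'
#' Labels an encounter from its assigned level, its outcome, and the
#' retrospectively verified ("truth") presentation. Under-triage clauses are
#' evaluated first — the patient-safety reading when an encounter could
#' match both — then over-triage; anything matching neither is appropriate.
#'
#' Under-triage:
#' * level 2 with an abnormal PAT or a need for an immediate life-saving
#'   intervention (`L2_ABNORMAL_PAT_OR_LSI`);
#' * level 3 with abnormal vital signs or a high-risk situation
#'   (`L3_ABNORMAL_VITALS_OR_RISK`);
#' * level 4 or 5 that used >= 2 resources or was admitted
#'   (`L45_GE2_RESOURCES_OR_ADMITTED`).
#'
#' Over-triage:
#' * level 1 not admitted (`L1_NOT_ADMITTED`);
#' * level 1-3 that used < 2 resources (`L123_LT2_RESOURCES`).
#'
#' Two rule sets are offered. `"strict_paper"` applies the resource clause
#' verbatim, so an admitted level-2 or level-3 patient who used fewer than
#' two resources is still over-triaged. `"reconciled"` (the default)
#' additionally exempts admitted patients from that clause: admission is
#' itself the justification for an urgent level, and this reading is the one
#' consistent with published per-level over-triage counts (see the methods
#' vignette).
#'
#' @param level Assigned triage level, integer 1-5.
#' @param outcome An [encounter_outcome()].
#' @param truth A [patient_presentation()] representing the retrospectively
#'   verified state (may differ from the triage-time assessment when
#'   criteria were missed), or `NULL` when no truth information is available
#'   (the under-triage clauses for levels 2-3 then cannot fire).
#' @param ref An `spt_config` used to judge the truth's vitals.
#' @param rule_set `"reconciled"` or `"strict_paper"`.
#' @return An `adjudication` list: `label` in
#'   `{"appropriate","over","under"}` and a `reason` code.
#' @examples
#' out <- encounter_outcome(2, "discharge")
#' adjudicate(4, out)$label  # level 4 with 2 resources: under-triage
#' @export
adjudicate <- function(level, outcome, truth = NULL,
                       ref = spt_reference_table(),
                       rule_set = c("reconciled", "strict_paper")) {
  rule_set <- match.arg(rule_set)
  level <- as.integer(level)
  stopifnot(level %in% 1:5, inherits(outcome, "encounter_outcome"))
  admitted <- outcome_admitted(outcome)

  truth_pat_or_lsi <- FALSE
  truth_vitals_or_risk <- FALSE
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "patient_presentation"))
    truth_pat_or_lsi <- pat_is_abnormal(truth$pat) ||
      truth$needs_lifesaving_intervention
    truth_vitals_or_risk <-
      length(vitals_abnormal(truth$vitals, truth$age_months, ref)) > 0 ||
      length(truth$high_risk_flags) > 0
  }

  label_one(level, outcome$resources_used, admitted,
            truth_pat_or_lsi, truth_vitals_or_risk, rule_set)
}

# Scalar/vector core of the adjudication rules; all arguments same length.
label_one <- function(level, resources_used, admitted,
                      truth_pat_or_lsi, truth_vitals_or_risk, rule_set) {
  n <- length(level)
  label <- rep("appropriate", n)
  reason <- rep("APPROPRIATE", n)

  under2 <- level == 2L & truth_pat_or_lsi
  under3 <- level == 3L & truth_vitals_or_risk
  under45 <- level >= 4L & (resources_used >= 2L | admitted)
  label[under2 | under3 | under45] <- "under"
  reason[under2] <- "L2_ABNORMAL_PAT_OR_LSI"
  reason[under3] <- "L3_ABNORMAL_VITALS_OR_RISK"
  reason[under45] <- "L45_GE2_RESOURCES_OR_ADMITTED"

  free <- label == "appropriate"
  over1 <- free & level == 1L & !admitted
  over123 <- free & !over1 & level <= 3L & resources_used < 2L &
    (rule_set == "strict_paper" | !admitted)
  label[over1 | over123] <- "over"
  reason[over1] <- "L1_NOT_ADMITTED"
  reason[over123] <- "L123_LT2_RESOURCES"

  if (n == 1) list(label = label, reason = reason)
  else data.frame(label = label, reason = reason, stringsAsFactors = FALSE)
}

#' Adjudicate every encounter in a cohort table
#'
#' Cohort-level wrapper. The truth used by the level-2/3 under-triage
#' clauses is the triage-time assessment overlaid with the optional
#' retrospective columns `retro_pat_abnormal`, `retro_lsi`,
#' `retro_vitals_abnormal`, `retro_high_risk` (logical): a criterion missed
#' at triage but documented on chart review fires the clause, exactly as a
#' retrospective adjudication of completed records would.
#'
#' @param cohort Data frame with `level`, outcome columns (`resources_used`,
#'   `disposition`, `ed_death`) and presentation columns.
#' @param ref An `spt_config`.
#' @param rule_set `"reconciled"` or `"strict_paper"` (see [adjudicate()]).
#' @return `cohort` with `adjudication` and `adjudication_reason` columns
#'   appended.
#' @export
adjudicate_cohort <- function(cohort, ref = spt_reference_table(),
                              rule_set = c("reconciled", "strict_paper")) {
  rule_set <- match.arg(rule_set)
  req <- c("level", "resources_used", "disposition")
  miss <- setdiff(req, names(cohort))
  if (length(miss) > 0) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ed_death <- if (is.null(cohort$ed_death)) rep(FALSE, nrow(cohort))
              else as.logical(cohort$ed_death)
  if (any(ed_death & cohort$disposition == "discharge")) {
    stop("inconsistent outcome: ed_death with disposition 'discharge'",
         call. = FALSE)
  }
  admitted <- cohort$disposition %in% c("ward", "icu", "ed_or")

  pat_ab <- (cohort$pat_appearance == "abnormal" |
             cohort$pat_breathing == "abnormal" |
             cohort$pat_circulation == "abnormal")
  lsi <- as.logical(cohort$lsi)
  vflags <- vitals_flags_cohort(cohort, ref)
  has_vflag <- lengths(vflags) > 0
  has_hflag <- !is.na(cohort$high_risk) & nzchar(cohort$high_risk)

  overlay <- function(base, col) {
    if (is.null(cohort[[col]])) base
    else base | (!is.na(cohort[[col]]) & as.logical(cohort[[col]]))
  }
  truth_pat_or_lsi <- overlay(overlay(pat_ab, "retro_pat_abnormal"),
                              "retro_lsi") | lsi
  truth_vitals_or_risk <- overlay(overlay(has_vflag, "retro_vitals_abnormal"),
                                  "retro_high_risk") | has_hflag

  lab <- label_one(as.integer(cohort$level),
                   as.integer(cohort$resources_used), admitted,
                   truth_pat_or_lsi, truth_vitals_or_risk, rule_set)
  cohort$adjudication <- lab$label
  cohort$adjudication_reason <- lab$reason
  cohort
}

#' Cohort adjudication rates
#'
#' Percentages of appropriate, over- and under-triaged encounters (summing
#' to 100 before rounding) plus per-level label counts.
#'
#' @param cohort An adjudicated cohort data frame (columns `level`,
#'   `adjudication`).
#' @param digits Decimal places for the displayed percentages; internal
#'   values are kept at full precision.
#' @return An `adjudication_rates` list: `n`, `counts` (named total counts),
#'   `percent` (full-precision), `percent_display` (rounded half-up to
#'   `digits`), and `by_level` (5x3 count matrix).
#' @export
adjudication_rates <- function(cohort, digits = 1) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("empty-input error: cohort must have at least one adjudicated row",
         call. = FALSE)
  }
  stopifnot(all(c("level", "adjudication") %in% names(cohort)))
  labels <- c("appropriate", "over", "under")
  counts <- vapply(labels, function(l) sum(cohort$adjudication == l),
                   numeric(1))
  n <- nrow(cohort)
  pct <- 100 * counts / n
  by_level <- t(vapply(1:5, function(lv) {
    vapply(labels, function(l) {
      sum(cohort$level == lv & cohort$adjudication == l)
    }, numeric(1))
  }, numeric(3)))
  rownames(by_level) <- paste0("level_", 1:5)
  structure(
    list(n = n, counts = counts, percent = pct,
         percent_display = round_half_up(pct, digits),
         by_level = by_level),
    class = "adjudication_rates"
  )
}

# Half-up decimal rounding (R's round() is round-half-even); printed
# clinical tables conventionally round 0.5 up.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.adjudication_rates <- function(x, ...) {
  cat("Adjudication of", x$n, "encounters\n")
  for (l in names(x$counts)) {
    cat(sprintf("  %-12s %4d (%.1f%%)\n", l, x$counts[[l]], x$percent[[l]]))
  }
  cat("Per-level counts (appropriate / over / under):\n")
  for (i in 1:5) {
    cat(sprintf("  level %d: %d / %d / %d\n", i,
                x$by_level[i, 1], x$by_level[i, 2], x$by_level[i, 3]))
  }
  invisible(x)
}
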