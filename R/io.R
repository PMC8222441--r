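#' Cohort CSV column dictionary
#'
#' The flat per-encounter record exchanged as CSV. Missing values (and only
#' missing values) are written as empty fields; unknown extra columns are
#' preserved on a read/write round-trip. Columns marked required are needed
#' by classification; outcome and retrospective columns are required only
#' by adjudication and validation.
#'
#' @return A `cohort_schema` data frame with `column`, `type`
#'   (`"integer"`, `"numeric"`, `"logical"`, `"character"`) and `required`.
#' @export
cohort_schema <- function() {
  s <- function(column, type, required) {
    data.frame(column = column, type = type, required = required,
               stringsAsFactors = FALSE)
  }
  rbind(
    s("encounter_id", "integer", FALSE),
    s("age_months", "integer", TRUE),
    s("sex", "character", FALSE),
    s("pat_appearance", "character", TRUE),
    s("pat_breathing", "character", TRUE),
    s("pat_circulation", "character", TRUE),
    s("lsi", "logical", TRUE),
    s("high_risk", "character", TRUE),
    s("temperature", "numeric", FALSE),
    s("heart_rate", "numeric", FALSE),
    s("respiratory_rate", "numeric", FALSE),
    s("systolic_bp", "numeric", FALSE),
    s("spo2", "numeric", FALSE),
    s("chief_complaint", "character", FALSE),
    s("trauma", "logical", FALSE),
    s("underlying_disease", "logical", FALSE),
    s("underlying_resp_disease", "logical", FALSE),
    s("accessory_muscle_use", "logical", FALSE),
    s("wheezing_rhonchi", "logical", FALSE),
    s("crying", "logical", FALSE),
    s("full_pulse", "logical", FALSE),
    s("full_consciousness", "logical", FALSE),
    s("predicted_resources", "integer", TRUE),
    s("level", "integer", FALSE),
    s("resources_used", "integer", FALSE),
    s("disposition", "character", FALSE),
    s("ed_death", "logical", FALSE),
    s("retro_pat_abnormal", "logical", FALSE),
    s("retro_lsi", "logical", FALSE),
    s("retro_vitals_abnormal", "logical", FALSE),
    s("retro_high_risk", "logical", FALSE),
    s("thai_ethnicity", "logical", FALSE),
    s("work_shift", "character", FALSE),
    s("workday", "logical", FALSE),
    s("self_transport", "logical", FALSE),
    s("nurse_experience_gt10y", "logical", FALSE),
    s("overcrowded", "logical", FALSE)
  )
}

#' Read a cohort CSV with schema validation
#'
#' Reads UTF-8 CSV, checks that every required column is present, coerces
#' typed columns, and collects row-level parse errors with their line
#' numbers. By default any row error aborts the read (all-or-nothing);
#' `skip_bad = TRUE` drops offending rows with a warning instead.
#'
#' @param path CSV file path.
#' @param schema A [cohort_schema()] data frame.
#' @param skip_bad Drop unparseable rows instead of failing.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path, schema = cohort_schema(), skip_bad = FALSE) {
  if (!file.exists(path)) {
    stop("schema error: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL,
                         fileEncoding = "UTF-8", check.names = FALSE)
  missing_req <- setdiff(schema$column[schema$required], names(raw))
  if (length(missing_req) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  bad <- list()
  out <- raw
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (!col %in% names(raw)) next
    x <- raw[[col]]
    x[x == ""] <- NA_character_
    parsed <- switch(schema$type[i],
      integer = suppressWarnings(as.integer(x)),
      numeric = suppressWarnings(as.numeric(x)),
      logical = parse_logical(x),
      character = x)
    fail <- which(!is.na(x) & is.na(parsed))
    if (length(fail) > 0) {
      bad[[col]] <- fail
    }
    out[[col]] <- parsed
  }
  if (length(bad) > 0) {
    msgs <- vapply(names(bad), function(col) {
      paste0(col, " (data line ", paste(utils::head(bad[[col]], 5) + 1,
                                        collapse = ", "), ")")
    }, character(1))
    bad_rows <- sort(unique(unlist(bad)))
    if (!skip_bad) {
      stop("row error: unparseable value(s) in ", paste(msgs, collapse = "; "),
           call. = FALSE)
    }
    warning("dropping ", length(bad_rows), " unparseable row(s): ",
            paste(msgs, collapse = "; "), call. = FALSE)
    out <- out[-bad_rows, , drop = FALSE]
    rownames(out) <- NULL
  }
  # high_risk uses "" (no flags), not NA
  if ("high_risk" %in% names(out)) {
    out$high_risk[is.na(out$high_risk)] <- ""
  }
  out
}

parse_logical <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

#' Write a cohort CSV
#'
#' Canonical formatting: UTF-8, missing values as empty fields, logicals as
#' `TRUE`/`FALSE`, no row names or quoting beyond what CSV requires.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full validation suite on an adjudicated cohort
#'
#' Computes, from one cohort: the screening 2x2 and its metrics, the
#' adjudication rates with per-level breakdown, the per-level resource and
#' disposition summaries, and the factor odds ratios. Adjudication is run
#' first if the cohort lacks an `adjudication` column.
#'
#' @param cohort Cohort data frame with `level` and outcome columns.
#' @param ref An `spt_config`.
#' @param rule_set Adjudication rule set (see [adjudicate()]).
#' @param ci_method Proportion CI method (see [screening_metrics()]).
#' @return An `spt_validation` list: `two_by_two`, `screening`, `rates`,
#'   `levels`, `factors`.
#' @examples
#' res <- spt_validate(replay_fixture())
#' res$screening
#' @export
spt_validate <- function(cohort, ref = spt_reference_table(),
                         rule_set = c("reconciled", "strict_paper"),
                         ci_method = c("clopper_pearson", "wilson")) {
  rule_set <- match.arg(rule_set)
  ci_method <- match.arg(ci_method)
  if (!"adjudication" %in% names(cohort)) {
    cohort <- adjudicate_cohort(cohort, ref, rule_set)
  }
  t22 <- two_by_two_from_cohort(cohort)
  structure(
    list(two_by_two = t22,
         screening = screening_metrics(t22, ci_method),
         rates = adjudication_rates(cohort),
         levels = level_summaries(cohort),
         factors = factor_odds_ratios(cohort),
         rule_set = rule_set),
    class = "spt_validation"
  )
}

#' @export
print.spt_validation <- function(x, ...) {
  print(x$screening)
  print(x$rates)
  print(x$levels)
  cat("Factor odds ratios for appropriate triage (Woolf 95% CI):\n")
  f <- x$factors
  for (i in seq_len(nrow(f))) {
    cat(sprintf("  %-24s %5.2f (%.2f-%.2f)\n", f$factor[i], f$or[i],
                f$ci_low[i], f$ci_high[i]))
  }
  invisible(x)
}

#' Write a validation report
#'
#' JSON reports are schema-stable and machine-parseable; markdown reports
#' mirror the layout of the standard validation cross-tabs.
#'
#' @param results An `spt_validation` object (or an empty list for a
#'   minimal document).
#' @param path Output file path.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_payload(results), path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    writeLines(report_markdown(results), path, useBytes = TRUE)
  }
  invisible(path)
}

report_payload <- function(results) {
  if (length(results) == 0) {
    return(list(report = "triage_validation", empty = TRUE))
  }
  stopifnot(inherits(results, "spt_validation"))
  s <- results$screening
  list(
    report = "triage_validation",
    rule_set = results$rule_set,
    two_by_two = results$two_by_two[c("tp", "fp", "fn", "tn")],
    screening = stats::setNames(lapply(seq_len(nrow(s)), function(i) {
      list(estimate = s$estimate[i], ci_low = s$ci_low[i],
           ci_high = s$ci_high[i], x = s$x[i], n = s$n[i],
           defined = s$defined[i])
    }), s$metric),
    adjudication = list(
      n = results$rates$n,
      counts = as.list(results$rates$counts),
      percent = as.list(results$rates$percent),
      by_level = apply(results$rates$by_level, 1, as.list)
    ),
    levels = list(
      n_by_level = results$levels$n_by_level,
      resources = apply(results$levels$resources, 1, as.list),
      disposition = apply(results$levels$disposition, 1, as.list),
      admission_rate_pct = results$levels$admission_rate_pct
    ),
    factor_odds_ratios = stats::setNames(lapply(
      seq_len(nrow(results$factors)), function(i) {
        f <- results$factors
        list(a = f$a[i], b = f$b[i], c = f$c[i], d = f$d[i],
             denominator = f$denominator[i], or = f$or[i],
             ci_low = f$ci_low[i], ci_high = f$ci_high[i])
      }), results$factors$factor)
  )
}

report_markdown <- function(results) {
  if (length(results) == 0) {
    return(c("# Triage validation report", "", "_No results._"))
  }
  stopifnot(inherits(results, "spt_validation"))
  s <- results$screening
  r <- results$rates
  lv <- results$levels
  f <- results$factors
  lines <- c("# Triage validation report", "",
             paste0("Rule set: ", results$rule_set, "; n = ", r$n), "",
             "## Screening performance", "",
             "| Metric | Estimate | 95% CI |", "|---|---|---|")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, if (s$defined[i]) {
      sprintf("| %s | %.2f%% | %.2f-%.2f |", s$metric[i],
              100 * s$estimate[i], 100 * s$ci_low[i], 100 * s$ci_high[i])
    } else sprintf("| %s | undefined | — |", s$metric[i]))
  }
  lines <- c(lines, "", "## Adjudication", "",
             sprintf("appropriate %d (%.1f%%), over %d (%.1f%%), under %d (%.1f%%)",
                     r$counts[["appropriate"]], r$percent[["appropriate"]],
                     r$counts[["over"]], r$percent[["over"]],
                     r$counts[["under"]], r$percent[["under"]]),
             "", "## Resources used by level", "",
             "| Level | n | >=2 | 1 | 0 |", "|---|---|---|---|---|")
  for (i in 1:5) {
    lines <- c(lines, sprintf("| %d | %d | %d (%s) | %d (%s) | %d (%s) |",
      i, lv$n_by_level[i],
      lv$resources[i, "ge2"], fmt_pct(lv$resources_pct[i, "ge2"]),
      lv$resources[i, "1"], fmt_pct(lv$resources_pct[i, "1"]),
      lv$resources[i, "0"], fmt_pct(lv$resources_pct[i, "0"])))
  }
  lines <- c(lines, "", "## Disposition by level", "",
             "| Level | n | ICU | Ward | ED OR | Discharge | Admission % |",
             "|---|---|---|---|---|---|---|")
  for (i in 1:5) {
    lines <- c(lines, sprintf("| %d | %d | %d | %d | %d | %d | %s |",
      i, lv$n_by_level[i], lv$disposition[i, "icu"], lv$disposition[i, "ward"],
      lv$disposition[i, "ed_or"], lv$disposition[i, "discharge"],
      fmt_pct(lv$admission_rate_pct[i])))
  }
  lines <- c(lines, "", "## Factor odds ratios (Woolf 95% CI)", "",
             "| Factor | a | b | c | d | OR | 95% CI |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(f))) {
    lines <- c(lines, sprintf("| %s | %d | %d | %d | %d | %.2f | %.2f-%.2f |",
      f$factor[i], f$a[i], f$b[i], f$c[i], f$d[i], f$or[i], f$ci_low[i],
      f$ci_high[i]))
  }
  lines
}
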