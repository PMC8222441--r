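#' Build the screening 2x2 table from a triaged cohort
#'
#' The instrument is treated as a binary screen: "urgent" means assigned
#' level 1-3, and the reference-standard positive outcome is hospital
#' admission (ward, ICU or ED operating room) or death in the ED.
#'
#' @param cohort Data frame with `level`, `disposition` and optionally
#'   `ed_death` columns.
#' @return A `two_by_two` list with integer cells `tp` (urgent, admitted or
#'   died), `fp` (urgent, discharged), `fn` (non-urgent, admitted or died),
#'   `tn` (non-urgent, discharged); cells sum to the cohort size.
#' @export
two_by_two_from_cohort <- function(cohort) {
  stopifnot(all(c("level", "disposition") %in% names(cohort)))
  ed_death <- if (is.null(cohort$ed_death)) rep(FALSE, nrow(cohort))
              else as.logical(cohort$ed_death)
  positive <- cohort$disposition %in% c("ward", "icu", "ed_or") | ed_death
  urgent <- cohort$level <= 3
  two_by_two(tp = sum(urgent & positive),  fp = sum(urgent & !positive),
             fn = sum(!urgent & positive), tn = sum(!urgent & !positive))
}

#' @rdname two_by_two_from_cohort
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("2x2 cells must be non-negative integers", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(cells), names(cells))),
            class = "two_by_two")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail via the beta quantile; by construction the
#' lower bound is 0 when `x = 0` and the upper bound is 1 when `x = n`.
#'
#' @param x Number of successes, `0 <= x <= n`.
#' @param n Number of trials, `> 0`.
#' @param level Two-sided confidence level (default 0.95).
#' @return Numeric `c(low, high)` in `[0, 1]`.
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      n <= 0 || x < 0 || x > n || x != floor(x) || n != floor(n)) {
    stop("clopper_pearson_ci: need integers 0 <= x <= n, n > 0", call. = FALSE)
  }
  alpha <- 1 - level
  low  <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Wilson score interval for a binomial proportion
#'
#' @inheritParams clopper_pearson_ci
#' @return Numeric `c(low, high)`.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  if (n <= 0 || x < 0 || x > n) {
    stop("wilson_ci: need 0 <= x <= n, n > 0", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Screening performance metrics with confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each with
#' a two-sided binomial confidence interval. A metric whose denominator is
#' zero is reported as undefined (`NA` with `defined = FALSE`), never
#' silently as 0.
#'
#' @param t A [two_by_two()] table.
#' @param ci_method `"clopper_pearson"` (default; exact) or `"wilson"`.
#' @param level Confidence level.
#' @return A `screening_result` data frame with columns `metric`,
#'   `estimate`, `ci_low`, `ci_high` (proportions in `[0, 1]`), `x`, `n`,
#'   `defined`.
#' @examples
#' screening_metrics(two_by_two(114, 298, 2, 106))
#' @export
screening_metrics <- function(t, ci_method = c("clopper_pearson", "wilson"),
                              level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  ci_method <- match.arg(ci_method)
  if (t$tp + t$fp + t$fn + t$tn == 0) {
    stop("empty 2x2 table", call. = FALSE)
  }
  ci_fun <- switch(ci_method,
                   clopper_pearson = clopper_pearson_ci,
                   wilson = wilson_ci)
  spec <- list(sensitivity = c(t$tp, t$tp + t$fn),
               specificity = c(t$tn, t$tn + t$fp),
               ppv = c(t$tp, t$tp + t$fp),
               npv = c(t$tn, t$tn + t$fn))
  rows <- lapply(names(spec), function(m) {
    x <- spec[[m]][1]; n <- spec[[m]][2]
    if (n == 0) {
      data.frame(metric = m, estimate = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, x = x, n = n, defined = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      ci <- ci_fun(x, n, level)
      data.frame(metric = m, estimate = x / n, ci_low = ci[[1]],
                 ci_high = ci[[2]], x = x, n = n, defined = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screening_result", "data.frame")
  attr(out, "ci_method") <- ci_method
  attr(out, "conf_level") <- level
  out
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Screening performance (", attr(x, "ci_method"), " ",
      100 * attr(x, "conf_level"), "% CI)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    if (!x$defined[i]) {
      cat(sprintf("  %-12s undefined (denominator 0)\n", x$metric[i]))
    } else {
      cat(sprintf("  %-12s %6.2f%% (%.2f-%.2f)  [%d/%d]\n", x$metric[i],
                  100 * x$estimate[i], 100 * x$ci_low[i], 100 * x$ci_high[i],
                  x$x[i], x$n[i]))
    }
  }
  invisible(x)
}

#' Odds ratio with Woolf log-normal confidence interval
#'
#' For a 2x2 factor table with cells `a` (factor present, group 1), `b`
#' (factor present, group 2), `c` (factor absent, group 1), `d` (factor
#' absent, group 2): `OR = (a d)/(b c)` and the Woolf interval is
#' `exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' With a zero cell the OR is undefined; setting `correction = TRUE` applies
#' the Haldane-Anscombe 0.5 continuity correction to every cell and flags
#' the result as corrected.
#'
#' @param a,b,c,d Non-negative integer cells.
#' @param level Confidence level.
#' @param correction Apply the 0.5 correction when a cell is zero.
#' @return List with `or`, `ci_low`, `ci_high`, `corrected`, `defined`.
#' @examples
#' odds_ratio(60, 5, 297, 158)  # OR 6.38 (2.51-16.22)
#' @export
odds_ratio <- function(a, b, c, d, level = 0.95, correction = FALSE) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("odds_ratio: cells must be non-negative", call. = FALSE)
  }
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correction) {
      return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  corrected = FALSE, defined = FALSE))
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       corrected = corrected, defined = TRUE)
}

# Registry of the factors tabulated against triage appropriateness.
# `denominator`: observational factors use the full cohort; factors derived
# from a recorded vital (SpO2 < 95%) are tabulated among encounters where
# that vital was recorded, which is the only policy consistent with
# published odds ratios for such factors.
factor_registry <- function() {
  data.frame(
    factor = c("underlying_resp_disease", "fever", "dyspnea", "diarrhea",
               "spo2_lt95", "accessory_muscle_use", "wheezing_rhonchi"),
    denominator = c("full_cohort", "full_cohort", "full_cohort",
                    "full_cohort", "recorded_only", "full_cohort",
                    "full_cohort"),
    stringsAsFactors = FALSE
  )
}

#' Factor odds ratios for triage appropriateness
#'
#' Cross-tabulates each registered factor against adjudicated
#' appropriateness (appropriate vs inappropriate = over + under) and
#' returns the unadjusted odds ratio of the factor for *appropriate* triage
#' with its Woolf interval. Chief-complaint factors (fever, dyspnea,
#' diarrhea) come from the `chief_complaint` column; `spo2_lt95` is derived
#' from the recorded saturation and uses recorded-only denominators; the
#' remaining factors are logical columns.
#'
#' @param cohort Adjudicated cohort data frame.
#' @param level Confidence level for the Woolf intervals.
#' @return A `factor_or_table` data frame: `factor`, cells `a` (factor,
#'   appropriate), `b` (factor, inappropriate), `c`, `d`, `denominator`,
#'   `or`, `ci_low`, `ci_high`.
#' @export
factor_odds_ratios <- function(cohort, level = 0.95) {
  stopifnot("adjudication" %in% names(cohort))
  appropriate <- cohort$adjudication == "appropriate"
  reg <- factor_registry()
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    f <- reg$factor[i]
    present <- switch(f,
      fever    = cohort$chief_complaint == "fever",
      dyspnea  = cohort$chief_complaint == "dyspnea",
      diarrhea = cohort$chief_complaint == "diarrhea",
      spo2_lt95 = !is.na(cohort$spo2) & cohort$spo2 < 95,
      underlying_resp_disease = as.logical(cohort$underlying_resp_disease),
      accessory_muscle_use = as.logical(cohort$accessory_muscle_use),
      wheezing_rhonchi = as.logical(cohort$wheezing_rhonchi))
    keep <- if (reg$denominator[i] == "recorded_only" && f == "spo2_lt95") {
      !is.na(cohort$spo2)
    } else rep(TRUE, nrow(cohort))
    a <- sum(keep & present & appropriate)
    b <- sum(keep & present & !appropriate)
    cc <- sum(keep & !present & appropriate)
    d <- sum(keep & !present & !appropriate)
    or <- odds_ratio(a, b, cc, d, level = level)
    data.frame(factor = f, a = a, b = b, c = cc, d = d,
               denominator = reg$denominator[i],
               or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("factor_or_table", "data.frame")
  out
}

#' Per-level resource and disposition summary tables
#'
#' Reproduces the two standard validation cross-tabs: resources used
#' (>= 2 / 1 / 0) by level, and disposition (ICU / ward / ED OR /
#' discharge) by level, with row percentages and the per-level admission
#' rate. Percentages for an empty level are undefined and rendered as `NA`.
#'
#' @param cohort Cohort data frame with `level`, `resources_used`,
#'   `disposition`.
#' @return A `level_summary` list with `resources` and `disposition` count
#'   matrices, matching `*_pct` percentage matrices, `n_by_level`, and
#'   `admission_rate_pct`.
#' @export
level_summaries <- function(cohort) {
  stopifnot(all(c("level", "resources_used", "disposition") %in% names(cohort)))
  lv <- factor(cohort$level, levels = 1:5)
  res_cat <- cut(cohort$resources_used, breaks = c(-Inf, 0, 1, Inf),
                 labels = c("0", "1", "ge2"))
  res_cat <- factor(res_cat, levels = c("ge2", "1", "0"))
  resources <- table(lv, res_cat)
  disp <- factor(cohort$disposition,
                 levels = c("icu", "ward", "ed_or", "discharge"))
  disposition <- table(lv, disp)
  n_by_level <- as.numeric(table(lv))
  pct <- function(m) {
    out <- 100 * sweep(unclass(m), 1, n_by_level, "/")
    out[n_by_level == 0, ] <- NA_real_
    out
  }
  admitted <- cohort$disposition %in% c("icu", "ward", "ed_or")
  adm <- vapply(1:5, function(l) sum(cohort$level == l & admitted), numeric(1))
  structure(
    list(resources = unclass(resources),
         resources_pct = pct(resources),
         disposition = unclass(disposition),
         disposition_pct = pct(disposition),
         n_by_level = n_by_level,
         admission_rate_pct = ifelse(n_by_level > 0,
                                     100 * adm / n_by_level, NA_real_)),
    class = "level_summary"
  )
}

#' @export
print.level_summary <- function(x, ...) {
  cat("Resources used by triage level (count, row %):\n")
  for (i in 1:5) {
    cat(sprintf("  level %d (n = %d): >=2: %d (%s)  1: %d (%s)  0: %d (%s)\n",
                i, x$n_by_level[i],
                x$resources[i, "ge2"], fmt_pct(x$resources_pct[i, "ge2"]),
                x$resources[i, "1"],  fmt_pct(x$resources_pct[i, "1"]),
                x$resources[i, "0"],  fmt_pct(x$resources_pct[i, "0"])))
  }
  cat("Admission rate by level (%):",
      paste(fmt_pct(x$admission_rate_pct), collapse = " / "), "\n")
  invisible(x)
}

fmt_pct <- function(p) ifelse(is.na(p), "—", sprintf("%.1f", p))
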