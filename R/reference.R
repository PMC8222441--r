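#' Age-banded vital-sign reference table
#'
#' The triage engine never hard-codes vital-sign cutoffs: it takes a
#' reference table of acceptable ranges per age band, normally loaded from a
#' site configuration file. `spt_reference_table()` returns the bundled
#' editable default, keyed to PaedCTAS-style pediatric age groups
#' (0-3 mo, 3-12 mo, 1-3 y, 3-6 y, 6-12 y, 12-15 y).
#'
#' Age bands are closed-open intervals `[low, high)` in months and must tile
#' `[0, 180)` contiguously. Acceptable ranges are closed intervals
#' `[low, high]`: a value exactly at a bound is within range, because
#' boundary vital signs are clinically "within normal limits".
#'
#' @param config Path to a YAML configuration file; defaults to the bundled
#'   configuration.
#' @return An object of class `spt_config`: a list with `reference_table`
#'   (data frame, one row per age band), `high_risk_registry`,
#'   `lsi_registry` and `provenance`.
#' @examples
#' cfg <- spt_reference_table()
#' cfg$reference_table[, c("low", "high", "hr_low", "hr_high")]
#' @export
spt_reference_table <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "spt_default_config.yaml",
                          package = "pedtriage", mustWork = TRUE)
  }
  read_spt_config(config)
}

#' Load and validate a triage configuration file
#'
#' Parses a YAML configuration holding the age-banded vital-sign reference
#' table and the high-risk / life-saving-intervention code registries, and
#' validates its structure: bands must be contiguous, non-overlapping and
#' cover all ages below 180 months, and every acceptable range must satisfy
#' `low < high`.
#'
#' @param path Path to the YAML file.
#' @return An `spt_config` object (see [spt_reference_table()]).
#' @export
read_spt_config <- function(path) {
  if (!file.exists(path)) {
    stop("config error: file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("config error: cannot parse ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  for (field in c("age_bands", "high_risk_registry", "lsi_registry")) {
    if (is.null(raw[[field]])) {
      stop("config error: missing field '", field, "'", call. = FALSE)
    }
  }
  bands <- raw$age_bands
  tab <- data.frame(
    low   = vapply(bands, function(b) as.numeric(b$low), numeric(1)),
    high  = vapply(bands, function(b) as.numeric(b$high), numeric(1)),
    label = vapply(bands, function(b) as.character(b$label), character(1)),
    stringsAsFactors = FALSE
  )
  for (v in spt_vital_names()) {
    rng <- lapply(bands, function(b) b[[v]])
    if (any(vapply(rng, is.null, logical(1)))) {
      stop("config error: band missing range for vital '", v, "'",
           call. = FALSE)
    }
    lo <- vapply(rng, function(r) as.numeric(r[[1]]), numeric(1))
    hi <- vapply(rng, function(r) as.numeric(r[[2]]), numeric(1))
    if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi)) {
      stop("config error: vital '", v, "' has a range with low >= high",
           call. = FALSE)
    }
    tab[[paste0(vital_abbrev(v), "_low")]]  <- lo
    tab[[paste0(vital_abbrev(v), "_high")]] <- hi
  }
  ord <- order(tab$low)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  if (tab$low[1] != 0 || tab$high[nrow(tab)] != 180 ||
      any(tab$high[-nrow(tab)] != tab$low[-1])) {
    stop("config error: age bands must tile [0, 180) months contiguously",
         call. = FALSE)
  }
  structure(
    list(reference_table   = tab,
         high_risk_registry = as.character(raw$high_risk_registry),
         lsi_registry       = as.character(raw$lsi_registry),
         provenance         = as.character(raw$provenance %||% "unspecified")),
    class = "spt_config"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

spt_vital_names <- function() {
  c("temperature", "heart_rate", "respiratory_rate", "systolic_bp", "spo2")
}

vital_abbrev <- function(v) {
  c(temperature = "temp", heart_rate = "hr", respiratory_rate = "rr",
    systolic_bp = "sbp", spo2 = "spo2")[[v]]
}

#' @export
print.spt_config <- function(x, ...) {
  cat("Triage configuration (", x$provenance, ")\n", sep = "")
  cat(nrow(x$reference_table), "age bands covering [0, 180) months\n")
  cat(length(x$high_risk_registry), "high-risk codes;",
      length(x$lsi_registry), "life-saving intervention codes\n")
  invisible(x)
}

# Map ages (months) to row indices of the reference table; error on ages
# outside coverage.
band_index <- function(age_months, ref) {
  tab <- ref$reference_table
  if (any(!is.finite(age_months)) ||
      any(age_months < tab$low[1]) || any(age_months >= tab$high[nrow(tab)])) {
    bad <- age_months[!is.finite(age_months) |
                        age_months < tab$low[1] |
                        age_months >= tab$high[nrow(tab)]]
    stop("coverage error: age ", paste(unique(bad), collapse = ", "),
         " months outside reference table coverage [", tab$low[1], ", ",
         tab$high[nrow(tab)], ")", call. = FALSE)
  }
  findInterval(age_months, tab$low)
}

#' Flag vital signs outside their age-band reference range
#'
#' Compares a set of recorded vital signs against the acceptable range for
#' the patient's age band. Missing (unrecorded) vitals never contribute a
#' flag: the instrument classifies on what was measured, and an unmeasured
#' vital is not evidence of abnormality.
#'
#' @param vitals A named list or one-row data frame with any of
#'   `temperature` (deg C), `heart_rate` (/min), `respiratory_rate` (/min),
#'   `systolic_bp` (mmHg), `spo2` (percent); `NA` means not recorded.
#' @param age_months Patient age in months; must lie within table coverage.
#' @param ref An `spt_config` object (default: bundled table).
#' @return Character vector of abnormal-vital codes such as `"spo2_low"` or
#'   `"heart_rate_high"`; empty when all recorded vitals are in range.
#' @examples
#' vitals_abnormal(list(spo2 = 93), age_months = 24)
#' @export
vitals_abnormal <- function(vitals, age_months, ref = spt_reference_table()) {
  stopifnot(inherits(ref, "spt_config"), length(age_months) == 1)
  i <- band_index(age_months, ref)
  tab <- ref$reference_table
  out <- character(0)
  for (v in spt_vital_names()) {
    x <- vitals[[v]]
    if (is.null(x) || length(x) == 0 || is.na(x)) next
    x <- as.numeric(x)
    if (x <= 0) stop("invalid vital '", v, "': must be positive, got ", x,
                     call. = FALSE)
    if (v == "spo2" && x > 100) stop("invalid spo2 > 100: ", x, call. = FALSE)
    ab <- vital_abbrev(v)
    if (x < tab[[paste0(ab, "_low")]][i])  out <- c(out, paste0(v, "_low"))
    if (x > tab[[paste0(ab, "_high")]][i]) out <- c(out, paste0(v, "_high"))
  }
  out
}

# Vectorised abnormal-vital flags over a cohort data frame. Returns a list of
# character vectors, one per row, in the canonical vital order.
vitals_flags_cohort <- function(df, ref) {
  n <- nrow(df)
  idx <- band_index(df$age_months, ref)
  tab <- ref$reference_table
  flags <- rep(list(character(0)), n)
  for (v in spt_vital_names()) {
    x <- df[[v]]
    if (is.null(x)) next
    x <- as.numeric(x)
    ok <- !is.na(x)
    if (any(x[ok] <= 0)) {
      stop("invalid vital '", v, "': values must be positive", call. = FALSE)
    }
    if (v == "spo2" && any(x[ok] > 100)) {
      stop("invalid spo2 > 100", call. = FALSE)
    }
    ab <- vital_abbrev(v)
    low  <- ok & x < tab[[paste0(ab, "_low")]][idx]
    high <- ok & x > tab[[paste0(ab, "_high")]][idx]
    for (j in which(low))  flags[[j]] <- c(flags[[j]], paste0(v, "_low"))
    for (j in which(high)) flags[[j]] <- c(flags[[j]], paste0(v, "_high"))
  }
  flags
}
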