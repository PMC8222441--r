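#' Deterministic 520-encounter replay fixture
#'
#' Builds, entirely in code, a 520-row cohort whose published margins are
#' exact: the level sizes (10/247/155/100/8), the level x resources-used
#' and level x disposition cross-tabs, the adjudication outcome under the
#' reconciled rules (357 appropriate, 149 over-triaged with per-level
#' counts 63/86, 14 under-triaged with per-level counts 3/1/10), and the
#' factor x appropriateness cross-tabs behind the reported odds ratios.
#'
#' Joint cells not pinned down by those margins are filled by a fixed,
#' documented convention (contiguous blocks per level and adjudication
#' group; cyclic offset fill for binary factors within each appropriateness
#' stratum), so everything beyond the published margins is reproducible
#' convention, not fabricated truth. The construction uses no random
#' numbers; two calls always return identical tables.
#'
#' Triage-time assessment columns are consistent with the assigned level
#' (a classification round-trip preserves all 520 levels); the 14
#' under-triaged encounters carry their missed criteria in the
#' retrospective columns (`retro_lsi`, `retro_high_risk`), mirroring
#' adjudication from completed charts: the 3 level-2 under-triages needed a
#' life-saving intervention (ICU admissions), the 1 level-3 under-triage
#' had an unrecognised high-risk situation, and the 10 level-4
#' under-triages used >= 2 resources (2 of them admitted).
#'
#' @return A 520-row cohort data frame in the standard column dictionary,
#'   including assigned `level` and outcome columns.
#' @examples
#' fx <- replay_fixture()
#' table(fx$level)
#' @export
replay_fixture <- function() {
  # --- per-level blocks: (n, resources_used, disposition, group) ----------
  blk <- function(level, n, res, disp, group) {
    data.frame(level = rep(level, n), resources_used = rep(res, n),
               disposition = rep(disp, n), group = rep(group, n),
               stringsAsFactors = FALSE)
  }
  blocks <- rbind(
    blk(1L, 4, 2L, "icu", "app"), blk(1L, 6, 2L, "ward", "app"),
    blk(2L, 47, 2L, "ward", "app"), blk(2L, 106, 2L, "discharge", "app"),
    blk(2L, 3, 2L, "icu", "under"),
    blk(2L, 28, 1L, "ward", "app"),
    blk(2L, 45, 1L, "discharge", "over"),
    blk(2L, 18, 0L, "discharge", "over"),
    blk(3L, 23, 2L, "ward", "app"), blk(3L, 2, 2L, "ed_or", "app"),
    blk(3L, 42, 2L, "discharge", "app"),
    blk(3L, 1, 1L, "ward", "app"),
    blk(3L, 1, 1L, "discharge", "under"),
    blk(3L, 64, 1L, "discharge", "over"),
    blk(3L, 22, 0L, "discharge", "over"),
    blk(4L, 2, 2L, "ward", "under"), blk(4L, 8, 2L, "discharge", "under"),
    blk(4L, 56, 1L, "discharge", "app"),
    blk(4L, 34, 0L, "discharge", "app"),
    blk(5L, 2, 1L, "discharge", "app"),
    blk(5L, 6, 0L, "discharge", "app")
  )
  n <- nrow(blocks)               # 520
  level <- blocks$level
  group <- blocks$group
  appropriate <- group == "app"
  app_rows <- which(appropriate)     # 357, fixture row order
  inapp_rows <- which(!appropriate)  # 163

  # --- triage-time assessment consistent with the assigned level ----------
  pat_appearance <- rep("normal", n)
  pat_breathing <- rep("normal", n)
  pat_circulation <- rep("normal", n)
  l1 <- which(level == 1L)
  pat_appearance[l1[1:6]] <- "abnormal"
  pat_breathing[l1[7:10]] <- "abnormal"

  # level-2 gates: a desaturation for the encounters behind the
  # SpO2 < 95% factor (26 appropriate, 4 over-triaged), a high-risk code
  # for every other level-2 encounter
  spo2_low <- rep(FALSE, n)
  l2_app <- intersect(which(level == 2L), app_rows)
  l2_over <- which(level == 2L & group == "over" & blocks$resources_used == 1L)
  spo2_low[l2_app[1:26]] <- TRUE
  spo2_low[l2_over[1:4]] <- TRUE
  high_risk <- rep("", n)
  high_risk[level == 2L & !spo2_low] <- "hr_sepsis_warning"

  # retrospective truth for the under-triaged
  retro_lsi <- level == 2L & group == "under"
  retro_high_risk <- level == 3L & group == "under"

  # --- stratified fills ----------------------------------------------------
  # cyclic fill: TRUE at k positions of a stratum starting at `offset`
  # (0-based), wrapping around; offsets decorrelate the factors
  fill <- function(rows, k, offset) {
    m <- length(rows)
    if (k == 0) return(integer(0))
    rows[(offset + 0:(k - 1)) %% m + 1]
  }
  strat <- function(k_app, k_inapp, offset) {
    v <- rep(FALSE, n)
    v[fill(app_rows, k_app, offset)] <- TRUE
    v[fill(inapp_rows, k_inapp, offset)] <- TRUE
    v
  }
  sex <- ifelse(strat(189, 90, 0), "male", "female")
  underlying_disease <- strat(93, 29, 11)
  trauma <- strat(70, 25, 29)
  crying <- strat(46, 20, 41)
  accessory_muscle_use <- strat(23, 3, 3)
  wheezing_rhonchi <- strat(85, 7, 57)
  full_pulse <- !strat(1, 0, 101)
  full_consciousness <- !strat(9, 4, 71)
  workday <- strat(196, 88, 7)
  self_transport <- strat(340, 158, 17)
  nurse_experience_gt10y <- strat(220, 108, 23)
  overcrowded <- strat(211, 96, 31)
  thai_ethnicity <- !strat(1, 1, 201)

  # respiratory subset of underlying disease: first 49 appropriate / 6
  # inappropriate carriers in stratum order (synthetic convention; counts
  # chosen so the factor's sample odds ratio matches the reported 4.16)
  underlying_resp_disease <- rep(FALSE, n)
  ud_app <- app_rows[underlying_disease[app_rows]]
  ud_inapp <- inapp_rows[underlying_disease[inapp_rows]]
  underlying_resp_disease[ud_app[1:49]] <- TRUE
  underlying_resp_disease[ud_inapp[1:6]] <- TRUE

  # chief complaints: contiguous segments within each stratum
  seg <- function(rows, counts) {
    out <- rep(NA_character_, n)
    stopifnot(sum(counts) == length(rows))
    out[rows] <- rep(names(counts), times = counts)
    out
  }
  cc_app <- seg(app_rows, c(
    fever = 123, dyspnea = 60, nausea_vomiting = 23, abdominal_pain = 14,
    diarrhea = 6, seizure = 9, altered_consciousness = 2, other = 120))
  cc_inapp <- seg(inapp_rows, c(
    fever = 76, dyspnea = 5, nausea_vomiting = 18, abdominal_pain = 11,
    diarrhea = 10, seizure = 1, other = 42))
  chief_complaint <- ifelse(appropriate, cc_app, cc_inapp)
  work_shift <- ifelse(appropriate,
                       seg(app_rows, c(morning = 85, evening = 198,
                                       night = 74)),
                       seg(inapp_rows, c(morning = 43, evening = 90,
                                         night = 30)))

  # --- ages: per-stratum quantile ladder with median 36, IQR 12-84 --------
  age_ladder <- function(m) {
    q <- (seq_len(m) - 0.5) / m
    knots_p <- c(0, 0.25, 0.5, 0.75, 1)
    knots_a <- c(1, 12, 36, 84, 179)
    round(stats::approx(knots_p, knots_a, xout = q)$y)
  }
  age_months <- integer(n)
  age_months[app_rows] <- age_ladder(length(app_rows))
  age_months[inapp_rows] <- age_ladder(length(inapp_rows))

  # --- vitals: in-range per age band; explicit missingness ----------------
  ref <- spt_reference_table()
  tab <- ref$reference_table
  bi <- band_index(age_months, ref)
  temperature <- rep(37.0, n)
  heart_rate <- round((tab$hr_low[bi] + tab$hr_high[bi]) / 2)
  respiratory_rate <- round((tab$rr_low[bi] + tab$rr_high[bi]) / 2)
  systolic_bp <- round((tab$sbp_low[bi] + tab$sbp_high[bi]) / 2)
  spo2 <- ifelse(spo2_low, 92, 98)

  # missing saturations placed away from level 2 so no gate is lost:
  # appropriate -> level-4 one-resource rows, inappropriate -> level-3
  # over-triage rows (18 + 6 = 24 missing, 4.6%)
  l4_app <- which(level == 4L & appropriate & blocks$resources_used == 1L)
  l3_over <- which(level == 3L & group == "over" & blocks$resources_used == 1L)
  spo2[l4_app[1:18]] <- NA_real_
  spo2[l3_over[1:6]] <- NA_real_
  # other vitals: cyclic missingness per stratum
  temperature[which(strat(12, 4, 60))] <- NA_real_
  systolic_bp[which(strat(13, 5, 90))] <- NA_real_
  heart_rate[which(strat(4, 0, 120))] <- NA_real_
  respiratory_rate[which(strat(18, 8, 150))] <- NA_real_

  data.frame(
    encounter_id = seq_len(n),
    age_months = age_months,
    sex = sex,
    thai_ethnicity = thai_ethnicity,
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
    trauma = trauma,
    underlying_disease = underlying_disease,
    underlying_resp_disease = underlying_resp_disease,
    accessory_muscle_use = accessory_muscle_use,
    wheezing_rhonchi = wheezing_rhonchi,
    crying = crying,
    full_pulse = full_pulse,
    full_consciousness = full_consciousness,
    predicted_resources = c(3L, 2L, 2L, 1L, 0L)[level],
    level = level,
    resources_used = blocks$resources_used,
    disposition = blocks$disposition,
    ed_death = FALSE,
    retro_pat_abnormal = FALSE,
    retro_lsi = retro_lsi,
    retro_vitals_abnormal = FALSE,
    retro_high_risk = retro_high_risk,
    work_shift = work_shift,
    workday = workday,
    self_transport = self_transport,
    nurse_experience_gt10y = nurse_experience_gt10y,
    overcrowded = overcrowded,
    stringsAsFactors = FALSE
  )
}
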