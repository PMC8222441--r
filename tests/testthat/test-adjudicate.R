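test_that("the documented adjudication examples label as specified", {
  # level 4 using two resources, discharged -> under-triage
  a <- adjudicate(4, encounter_outcome(2, "discharge"))
  expect_equal(a$label, "under")
  expect_equal(a$reason, "L45_GE2_RESOURCES_OR_ADMITTED")

  # level 1 discharged -> over-triage regardless of resources
  b <- adjudicate(1, encounter_outcome(3, "discharge"))
  expect_equal(b$label, "over")
  expect_equal(b$reason, "L1_NOT_ADMITTED")

  # level 5 with no resources, discharged -> appropriate
  c_ <- adjudicate(5, encounter_outcome(0, "discharge"))
  expect_equal(c_$label, "appropriate")

  # admitted level 2 with one resource: rule sets disagree
  out <- encounter_outcome(1, "ward")
  expect_equal(adjudicate(2, out, rule_set = "reconciled")$label,
               "appropriate")
  expect_equal(adjudicate(2, out, rule_set = "strict_paper")$label, "over")

  # level 2 whose truth needed a life-saving intervention -> under, even
  # though it also used < 2 resources (under-triage takes precedence)
  truth <- patient_presentation(24, needs_lifesaving_intervention = TRUE)
  d <- adjudicate(2, encounter_outcome(1, "discharge"), truth)
  expect_equal(d$label, "under")
  expect_equal(d$reason, "L2_ABNORMAL_PAT_OR_LSI")

  # level 3 whose truth had an out-of-range vital -> under
  truth3 <- patient_presentation(24, vitals = vital_signs(spo2 = 90))
  expect_equal(adjudicate(3, encounter_outcome(1, "discharge"), truth3)$label,
               "under")
})

test_that("labels partition every randomized input and match the predicate oracle", {
  set.seed(11)
  for (rules in c("reconciled", "strict_paper")) {
    d <- rand_outcomes(3000)
    cohort <- data.frame(
      level = d$level,
      resources_used = d$resources_used,
      disposition = d$disposition,
      age_months = 24L,
      pat_appearance = "normal", pat_breathing = "normal",
      pat_circulation = "normal", lsi = FALSE, high_risk = "",
      retro_lsi = d$truth_pat_or_lsi,
      retro_high_risk = d$truth_vitals_or_risk,
      stringsAsFactors = FALSE
    )
    got <- adjudicate_cohort(cohort, rule_set = rules)$adjudication
    admitted <- d$disposition %in% c("ward", "icu", "ed_or")
    want <- mapply(oracle_label, d$level, d$resources_used, admitted,
                   d$truth_pat_or_lsi, d$truth_vitals_or_risk,
                   MoreArgs = list(rules = rules))
    expect_identical(got, unname(want))
    expect_true(all(got %in% c("appropriate", "over", "under")))
    # level-5 encounters are never over-triaged
    expect_false(any(got[d$level == 5] == "over"))
    # reconciled: admitted level-1 patients never over-triaged
    if (rules == "reconciled") {
      expect_false(any(got[d$level == 1 & admitted] == "over"))
    }
  }
})

test_that("cohort rates sum to 100% and report per-level counts", {
  cohort <- data.frame(
    level = c(2L, 2L, 4L),
    adjudication = c("appropriate", "over", "under"))
  r <- adjudication_rates(cohort)
  expect_equal(sum(r$percent), 100)
  expect_equal(unname(r$counts), c(1, 1, 1))
  expect_equal(r$by_level["level_2", "over"], 1)
  expect_equal(r$by_level["level_4", "under"], 1)

  single <- adjudication_rates(
    data.frame(level = 3L, adjudication = "appropriate"))
  expect_equal(unname(single$percent), c(100, 0, 0))

  expect_error(adjudication_rates(data.frame()), "empty-input")
})

test_that("a 357/149/14 split reports 68.7 / 28.7 / 2.7 at one decimal", {
  cohort <- data.frame(
    level = 2L,
    adjudication = rep(c("appropriate", "over", "under"), c(357, 149, 14)))
  r <- adjudication_rates(cohort, digits = 1)
  expect_equal(unname(r$percent_display), c(68.7, 28.7, 2.7))
  expect_equal(sum(r$percent), 100)
})

test_that("an ED death recorded with a discharge disposition is rejected", {
  expect_error(encounter_outcome(2, "discharge", ed_death = TRUE),
               "inconsistent")
  cohort <- data.frame(level = 1L, resources_used = 2L,
                       disposition = "discharge", ed_death = TRUE,
                       age_months = 24L, pat_appearance = "normal",
                       pat_breathing = "normal", pat_circulation = "normal",
                       lsi = FALSE, high_risk = "")
  expect_error(adjudicate_cohort(cohort), "inconsistent")
})
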