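cfg <- spt_reference_table()

test_that("the five-level ladder assigns the documented levels", {
  # abnormal PAT dominates everything else
  p1 <- patient_presentation(24, pat = pat_assessment(appearance = "abnormal"),
                             predicted_resources = 0)
  r1 <- spt_classify(p1, cfg)
  expect_equal(r1$level, 1L)
  expect_equal(r1$rationale, "pat_appearance_abnormal")
  expect_equal(r1$time_target_minutes, 0)

  # >= 2 predicted resources with a clean screen -> level 3
  p3 <- patient_presentation(24, vitals = vital_signs(spo2 = 98),
                             predicted_resources = 2)
  r3 <- spt_classify(p3, cfg)
  expect_equal(r3$level, 3L)
  expect_equal(r3$time_target_minutes, 60)

  # nothing at all -> level 5
  p5 <- patient_presentation(24, predicted_resources = 0)
  expect_equal(spt_classify(p5, cfg)$level, 5L)
  expect_true(is.na(spt_classify(p5, cfg)$time_target_minutes))

  # an out-of-range vital overrides the resource ladder
  p2 <- patient_presentation(24, vitals = vital_signs(heart_rate = 190),
                             predicted_resources = 0)
  r2 <- spt_classify(p2, cfg)
  expect_equal(r2$level, 2L)
  expect_equal(r2$rationale, "vital_heart_rate_high")
  expect_equal(r2$time_target_minutes, 10)

  # need for a life-saving intervention alone mandates level 1
  plsi <- patient_presentation(24, needs_lifesaving_intervention = TRUE)
  expect_equal(spt_classify(plsi, cfg)$rationale, "lifesaving_intervention")

  # a high-risk situation alone places level 2
  phr <- patient_presentation(24, high_risk_flags = "hr_sepsis_warning",
                              predicted_resources = 1)
  expect_equal(spt_classify(phr, cfg)$level, 2L)
})

test_that("every randomized presentation maps to exactly one level in 1..5", {
  set.seed(42)
  cohort <- rand_presentations(2000)
  out <- classify_cohort(cohort, cfg)
  expect_equal(nrow(out), 2000)
  expect_true(all(out$level %in% 1:5))
  expect_true(all(!is.na(out$level)))
  expect_true(all(nzchar(out$rationale)))
  # time targets follow the level
  expect_true(all(out$time_target_minutes[out$level == 1] == 0))
  expect_true(all(out$time_target_minutes[out$level == 2] == 10))
  expect_true(all(out$time_target_minutes[out$level == 3] == 60))
  expect_true(all(is.na(out$time_target_minutes[out$level >= 4])))
})

test_that("adding any single abnormality never de-escalates", {
  set.seed(7)
  base <- rand_presentations(500)
  lv0 <- classify_cohort(base, cfg)$level
  flips <- list(
    function(d) { d$pat_appearance <- "abnormal"; d },
    function(d) { d$pat_circulation <- "abnormal"; d },
    function(d) { d$lsi <- TRUE; d },
    function(d) { d$high_risk <- "hr_altered_mental_state"; d },
    function(d) { d$spo2 <- 92; d }
  )
  for (flip in flips) {
    lv1 <- classify_cohort(flip(base), cfg)$level
    expect_true(all(lv1 <= lv0))
  }
})

test_that("level is a non-increasing step function of predicted resources", {
  for (res in 0:5) {
    p <- patient_presentation(60, predicted_resources = res)
    expect_equal(spt_classify(p, cfg)$level,
                 if (res >= 2) 3L else if (res == 1) 4L else 5L)
  }
})

test_that("classification is deterministic including rationale order", {
  p <- patient_presentation(
    6, pat = pat_assessment(appearance = "abnormal",
                            work_of_breathing = "abnormal"),
    needs_lifesaving_intervention = TRUE)
  r1 <- spt_classify(p, cfg)
  r2 <- spt_classify(p, cfg)
  expect_identical(r1, r2)
  expect_equal(r1$rationale, c("pat_appearance_abnormal",
                               "pat_breathing_abnormal",
                               "lifesaving_intervention"))
  # level 2: vitals logged before high-risk codes, flags sorted
  p2 <- patient_presentation(24, vitals = vital_signs(spo2 = 90),
                             high_risk_flags = c("hr_b", "hr_a"))
  expect_equal(spt_classify(p2, cfg)$rationale,
               c("vital_spo2_low", "high_risk_hr_a", "high_risk_hr_b"))
})

test_that("strict mode flags unmeasured vitals without changing the level", {
  p <- patient_presentation(24, vitals = vital_signs(spo2 = NA),
                            predicted_resources = 2)
  relaxed <- spt_classify(p, cfg)
  strict <- spt_classify(p, cfg, strict = TRUE)
  expect_equal(strict$level, relaxed$level)
  expect_true("unmeasured_vitals" %in% strict$rationale)
  expect_false("unmeasured_vitals" %in% relaxed$rationale)
})

test_that("presentation invariants are enforced at construction", {
  expect_error(patient_presentation(180), "age_months")
  expect_error(patient_presentation(-1), "age_months")
  expect_error(patient_presentation(24, predicted_resources = -1),
               "predicted_resources")
  expect_error(vital_signs(spo2 = 101), "spo2")
  expect_error(vital_signs(heart_rate = 0), "positive")
  expect_error(pat_assessment(appearance = "fine"), "PAT arm")
})
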