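fx <- replay_fixture()

test_that("the replay fixture reproduces the level x resources cross-tab", {
  ls <- level_summaries(fx)
  expect_equal(unname(ls$resources),
               matrix(c(10, 0, 0,
                        156, 73, 18,
                        67, 66, 22,
                        10, 56, 34,
                        0, 2, 6), nrow = 5, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("the replay fixture reproduces the level x disposition cross-tab", {
  ls <- level_summaries(fx)
  # icu / ward / ed_or / discharge per level
  expect_equal(unname(ls$disposition),
               matrix(c(4, 6, 0, 0,
                        3, 75, 0, 169,
                        0, 24, 2, 129,
                        0, 2, 0, 98,
                        0, 0, 0, 8), nrow = 5, byrow = TRUE),
               ignore_attr = TRUE)
  # 78 admissions among 247 level-2 encounters, 3 of them ICU
  expect_equal(sum(fx$level == 2 & fx$disposition != "discharge"), 78)
  expect_equal(sum(fx$level == 2 & fx$disposition == "icu"), 3)
})

test_that("reconciled adjudication of the fixture gives 357/149/14 with the published per-level counts", {
  ad <- adjudicate_cohort(fx, rule_set = "reconciled")
  r <- adjudication_rates(ad)
  expect_equal(unname(r$counts), c(357, 149, 14))
  expect_equal(unname(r$by_level[, "over"]), c(0, 63, 86, 0, 0))
  expect_equal(unname(r$by_level[, "under"]), c(0, 3, 1, 10, 0))
})

test_that("a classification round-trip preserves all 520 assigned levels", {
  cl <- classify_cohort(fx[setdiff(names(fx), "level")])
  expect_equal(cl$level, fx$level)
})

test_that("factor cross-tabs match the published appropriateness margins", {
  ad <- adjudicate_cohort(fx)
  f <- factor_odds_ratios(ad)
  cells <- function(name) unlist(f[f$factor == name, c("a", "b", "c", "d")])
  expect_equal(unname(cells("fever")), c(123, 76, 234, 87))
  expect_equal(unname(cells("dyspnea")), c(60, 5, 297, 158))
  expect_equal(unname(cells("diarrhea")), c(6, 10, 351, 153))
  expect_equal(unname(cells("spo2_lt95")), c(26, 4, 313, 153))
  expect_equal(unname(cells("accessory_muscle_use")), c(23, 3, 334, 160))
  expect_equal(unname(cells("wheezing_rhonchi")), c(85, 7, 272, 156))
  # saturation recorded for 339 appropriate / 157 inappropriate encounters
  app <- ad$adjudication == "appropriate"
  expect_equal(sum(!is.na(fx$spo2) & app), 339)
  expect_equal(sum(!is.na(fx$spo2) & !app), 157)
})

test_that("auxiliary descriptive margins follow the calibration", {
  ad <- adjudicate_cohort(fx)
  app <- ad$adjudication == "appropriate"
  expect_equal(c(sum(fx$sex == "male" & app), sum(fx$sex == "male" & !app)),
               c(189, 90))
  expect_equal(c(sum(fx$underlying_disease & app),
                 sum(fx$underlying_disease & !app)), c(93, 29))
  expect_equal(c(sum(fx$trauma & app), sum(fx$trauma & !app)), c(70, 25))
  expect_equal(sum(fx$pat_appearance == "abnormal"), 6)
  expect_equal(sum(fx$pat_breathing == "abnormal"), 4)
  expect_equal(sum(fx$pat_circulation == "abnormal"), 0)
  # abnormal PAT occurs only in level 1, all appropriate
  pat_ab <- fx$pat_appearance == "abnormal" | fx$pat_breathing == "abnormal"
  expect_true(all(fx$level[pat_ab] == 1))
  expect_true(all(app[pat_ab]))
  # ages: median 36 months, quartiles near 12 and 84, in both strata
  for (sel in list(app, !app)) {
    expect_equal(median(fx$age_months[sel]), 36)
    q <- unname(quantile(fx$age_months[sel], c(0.25, 0.75)))
    expect_lt(abs(q[1] - 12), 2)
    expect_lt(abs(q[2] - 84), 2)
  }
  expect_false(any(fx$ed_death))
})

test_that("the fixture is bit-stable (golden margins)", {
  expect_identical(replay_fixture(), fx)
  # frozen fingerprint of the joint fill: per-column checksums
  num_cols <- vapply(fx, is.numeric, logical(1))
  sums <- vapply(fx[num_cols], function(x) sum(x, na.rm = TRUE), numeric(1))
  expect_equal(unname(sums[c("age_months", "resources_used",
                             "predicted_resources", "level")]),
               c(28866, 683, 934, 1409))
})
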