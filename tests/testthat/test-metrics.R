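test_that("the 2x2 from the published disposition cross-tab is 114/298/2/106", {
  t <- two_by_two_from_cohort(disposition_cohort())
  expect_equal(t$tp, 114)
  expect_equal(t$fp, 298)
  expect_equal(t$fn, 2)
  expect_equal(t$tn, 106)
})

test_that("2x2 cells conserve cohort size and match brute-force filtering", {
  set.seed(3)
  for (rep in 1:5) {
    d <- rand_outcomes(500)
    d$ed_death <- d$disposition != "discharge" & runif(500) < 0.02
    t <- two_by_two_from_cohort(d)
    expect_equal(t$tp + t$fp + t$fn + t$tn, nrow(d))
    pos <- d$disposition != "discharge" | d$ed_death
    expect_equal(t$tp, sum(d$level <= 3 & pos))
    expect_equal(t$fn, sum(d$level >= 4 & pos))
    expect_equal(t$tn, sum(d$level >= 4 & !pos))
  }
  expect_equal(two_by_two_from_cohort(
    data.frame(level = 4:5, disposition = "discharge"))$tp, 0)
})

test_that("screening metrics reproduce the direct ratios with exact CIs", {
  s <- screening_metrics(two_by_two(114, 298, 2, 106))
  est <- setNames(s$estimate, s$metric)
  expect_equal(round(100 * est[["sensitivity"]], 2), 98.28)
  expect_equal(round(100 * est[["specificity"]], 2), 26.24)
  expect_equal(round(100 * est[["ppv"]], 2), 27.67)
  expect_equal(round(100 * est[["npv"]], 2), 98.15)
  expect_true(all(s$ci_low <= s$estimate & s$estimate <= s$ci_high))

  # perfect classifier
  perfect <- screening_metrics(two_by_two(20, 0, 0, 30))
  expect_equal(perfect$estimate, rep(1, 4))

  # random cells against full-precision ratio arithmetic
  set.seed(5)
  for (i in 1:20) {
    cells <- rpois(4, 50) + 1
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    s <- screening_metrics(t)
    expect_equal(s$estimate,
                 c(t$tp / (t$tp + t$fn), t$tn / (t$tn + t$fp),
                   t$tp / (t$tp + t$fp), t$tn / (t$tn + t$fn)))
    # prevalence identity: ppv*(tp+fp) + npv*(tn+fn) = tp + tn
    expect_equal(s$estimate[3] * (t$tp + t$fp) + s$estimate[4] * (t$tn + t$fn),
                 t$tp + t$tn)
  }
})

test_that("a zero denominator yields an undefined metric, not 0", {
  s <- screening_metrics(two_by_two(0, 0, 0, 10))  # no positives, no urgent
  expect_false(s$defined[s$metric == "sensitivity"])
  expect_false(s$defined[s$metric == "ppv"])
  expect_true(is.na(s$estimate[s$metric == "sensitivity"]))
  expect_true(s$defined[s$metric == "specificity"])
})

test_that("Clopper-Pearson hits the boundary cases and the binomial-tail oracle", {
  expect_equal(clopper_pearson_ci(0, 10)[["low"]], 0)
  expect_equal(clopper_pearson_ci(10, 10)[["high"]], 1)
  ci <- clopper_pearson_ci(114, 116)
  oracle <- cp_bisect(114, 116)
  expect_equal(unname(ci), oracle, tolerance = 1e-9)
  expect_error(clopper_pearson_ci(5, 4), "x <= n")
  expect_error(clopper_pearson_ci(-1, 4), "x <= n")
})

test_that("Wilson interval brackets the point estimate and stays in [0, 1]", {
  for (x in c(0, 1, 57, 116)) {
    ci <- wilson_ci(x, 116)
    expect_true(ci[["low"]] <= x / 116 && x / 116 <= ci[["high"]])
    expect_true(ci[["low"]] >= 0 && ci[["high"]] <= 1)
  }
})

test_that("odds ratios and Woolf intervals reproduce the reference factors", {
  dysp <- odds_ratio(60, 5, 297, 158)
  expect_equal(round(dysp$or, 2), 6.38)
  expect_equal(round(dysp$ci_low, 2), 2.51)
  expect_equal(round(dysp$ci_high, 2), 16.22)

  sao2 <- odds_ratio(26, 4, 313, 153)  # recorded-only denominators
  expect_equal(round(sao2$or, 2), 3.18)
  expect_equal(round(sao2$ci_low, 2), 1.09)
  expect_equal(round(sao2$ci_high, 2), 9.27)

  # no association when rows are proportional
  expect_equal(odds_ratio(10, 5, 40, 20)$or, 1)
})

test_that("Woolf CI properties: contains the OR, inverts, narrows under scaling", {
  set.seed(9)
  for (i in 1:50) {
    cells <- rpois(4, 30) + 1
    o <- odds_ratio(cells[1], cells[2], cells[3], cells[4])
    expect_true(o$ci_low < o$or && o$or < o$ci_high)
    # swapping factor rows inverts the OR exactly
    inv <- odds_ratio(cells[2], cells[1], cells[4], cells[3])
    expect_equal(inv$or, 1 / o$or)
    expect_equal(inv$ci_low, 1 / o$ci_high)
    # scaling every cell by k > 1 shrinks the log-width
    sc <- odds_ratio(3 * cells[1], 3 * cells[2], 3 * cells[3], 3 * cells[4])
    expect_lt(log(sc$ci_high / sc$ci_low), log(o$ci_high / o$ci_low))
  }
})

test_that("a zero cell gives an undefined OR unless the correction is enabled", {
  o <- odds_ratio(5, 0, 10, 20)
  expect_false(o$defined)
  expect_true(is.na(o$or))
  oc <- odds_ratio(5, 0, 10, 20, correction = TRUE)
  expect_true(oc$defined)
  expect_true(oc$corrected)
  expect_equal(oc$or, (5.5 * 20.5) / (0.5 * 10.5))
})

test_that("level summaries reproduce the resource cross-tab rows", {
  fx <- replay_fixture()
  ls <- level_summaries(fx)
  expect_equal(unname(ls$resources[2, ]), c(156, 73, 18))
  expect_equal(round(unname(ls$resources_pct[2, ]), 1), c(63.2, 29.6, 7.3))
  expect_equal(unname(ls$n_by_level), c(10, 247, 155, 100, 8))
  expect_equal(round(ls$admission_rate_pct, 1), c(100, 31.6, 16.8, 2, 0))
  # each row sums to its level count
  expect_equal(unname(rowSums(ls$resources)), ls$n_by_level)
  expect_equal(unname(rowSums(ls$disposition)), ls$n_by_level)
  # an empty level renders undefined percentages
  ls2 <- level_summaries(data.frame(level = 2L, resources_used = 1L,
                                    disposition = "ward"))
  expect_true(all(is.na(ls2$resources_pct[1, ])))
  expect_true(is.na(ls2$admission_rate_pct[5]))
})
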