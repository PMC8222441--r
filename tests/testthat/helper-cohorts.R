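# Shared builders and independent oracles.

# Random presentation cohort (base R RNG; callers set the seed).
rand_presentations <- function(n) {
  arm <- function() sample(c("normal", "abnormal", "not_assessed"), n,
                           replace = TRUE, prob = c(0.8, 0.1, 0.1))
  maybe <- function(x, p_na = 0.2) ifelse(runif(n) < p_na, NA_real_, x)
  data.frame(
    age_months = sample(0:179, n, replace = TRUE),
    pat_appearance = arm(),
    pat_breathing = arm(),
    pat_circulation = arm(),
    lsi = runif(n) < 0.05,
    high_risk = ifelse(runif(n) < 0.2, "hr_sepsis_warning", ""),
    temperature = maybe(round(runif(n, 35, 41), 1)),
    heart_rate = maybe(round(runif(n, 40, 220))),
    respiratory_rate = maybe(round(runif(n, 5, 80))),
    systolic_bp = maybe(round(runif(n, 45, 180))),
    spo2 = maybe(round(runif(n, 85, 100))),
    predicted_resources = sample(0:4, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Random adjudication inputs: levels, outcomes and truth flags.
rand_outcomes <- function(n) {
  data.frame(
    level = sample(1:5, n, replace = TRUE),
    resources_used = sample(0:4, n, replace = TRUE),
    disposition = sample(c("discharge", "ward", "icu", "ed_or"), n,
                         replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)),
    truth_pat_or_lsi = runif(n) < 0.15,
    truth_vitals_or_risk = runif(n) < 0.25,
    stringsAsFactors = FALSE
  )
}

# Independent re-statement of the adjudication definitions as flat
# predicates, evaluated per row (oracle for the rule engine).
oracle_label <- function(level, resources_used, admitted,
                         truth_pat_or_lsi, truth_vitals_or_risk, rules) {
  if (level == 2 && truth_pat_or_lsi) return("under")
  if (level == 3 && truth_vitals_or_risk) return("under")
  if (level %in% 4:5 && (resources_used >= 2 || admitted)) return("under")
  if (level == 1 && !admitted) return("over")
  if (level %in% 1:3 && resources_used < 2 &&
      (rules == "strict_paper" || !admitted)) return("over")
  "appropriate"
}

# Exact binomial interval by bisection on the binomial tail (oracle for the
# beta-quantile implementation).
cp_bisect <- function(x, n, level = 0.95, tol = 1e-12) {
  alpha <- 1 - level
  bis <- function(f, lo, hi) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  low <- if (x == 0) 0 else
    bis(function(p) 1 - pbinom(x - 1, n, p) < alpha / 2, 0, 1)
  high <- if (x == n) 1 else
    bis(function(p) pbinom(x, n, p) > alpha / 2, 0, 1)
  c(low, high)
}

# Cohort shaped like the published level x disposition cross-tab.
disposition_cohort <- function() {
  rows <- rbind(
    c(1, "icu", 4), c(1, "ward", 6),
    c(2, "icu", 3), c(2, "ward", 75), c(2, "discharge", 169),
    c(3, "ward", 24), c(3, "ed_or", 2), c(3, "discharge", 129),
    c(4, "ward", 2), c(4, "discharge", 98),
    c(5, "discharge", 8)
  )
  data.frame(
    level = rep(as.integer(rows[, 1]), times = as.integer(rows[, 3])),
    disposition = rep(rows[, 2], times = as.integer(rows[, 3])),
    ed_death = FALSE,
    stringsAsFactors = FALSE
  )
}
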