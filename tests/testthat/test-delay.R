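uniform12_curve <- function() {
  monthly_risk_curve(c(0, cumsum(rep(1 / 12, 12)), rep(1, 48)), group = "I",
                     estimator = "toy")
}

test_that("delay is the wait until the next scheduled visit", {
  s <- surveillance_schedule("toy", c(3, 9, 12))
  expect_equal(detection_delay(6, s), 3L)       # the worked example
  expect_equal(detection_delay(9, surveillance_schedule("one", 9)), 0L)
  # failures after the last visit run to the horizon sentinel (month 61)
  expect_equal(detection_delay(59, surveillance_schedule("early", c(12, 24, 36, 48))),
               2L)
  empty <- surveillance_schedule("none", integer(0))
  expect_equal(detection_delay(c(1, 30, 60), empty), c(60L, 31L, 1L))
  expect_error(detection_delay(0, s), "1..60")
  expect_error(detection_delay(61, s), "1..60")
})

test_that("expected total delay matches closed-form and brute-force enumeration", {
  # monthly surveillance detects everything instantly
  all_months <- surveillance_schedule("monthly", 1:60)
  cv <- profile_curve(fx_profiles_nocens()[["IV"]])
  expect_equal(expected_total_delay(cv, all_months)$total_delay, 0)

  # uniform failures over a year, one visit at month 12: mean wait 5.5 months
  r <- expected_total_delay(uniform12_curve(), surveillance_schedule("annual", 12),
                            n = 1)
  expect_equal(r$total_delay, 5.5)
  expect_equal(r$expected_delay_per_failure, 5.5)

  # exact expectation equals an independent enumeration over failure months
  set.seed(501)
  for (i in 1:20) {
    Fv <- cummax(c(0, sort(stats::runif(60, 0, 0.5))))
    cv <- monthly_risk_curve(Fv, "II", estimator = "rand")
    s <- surveillance_schedule("rand", sort(sample(60, sample(1:10, 1))))
    brute <- 0
    for (m in 1:60) {
      nxt <- c(s$visit_months[s$visit_months >= m], 61)[1]
      brute <- brute + cv$p[m] * (nxt - m)
    }
    expect_equal(expected_total_delay(cv, s, n = 1000)$total_delay, 1000 * brute)
  }
})

test_that("Monte-Carlo delay agrees with the exact expectation and is seeded", {
  cv <- profile_curve(fx_profiles_nocens()[["III"]])
  s <- control_schedule("nccn_least")
  exact <- expected_total_delay(cv, s, n = 1000)
  sim <- simulate_total_delay(cv, s, n = 1000, seed = 77)
  expect_identical(simulate_total_delay(cv, s, n = 1000, seed = 77)$total_delay,
                   sim$total_delay)
  # 3-standard-error band for the sum of n iid per-patient delays
  d <- detection_delay(1:60, s)
  m1 <- sum(cv$p * d); m2 <- sum(cv$p * d^2)
  se <- sqrt(1000 * (m2 - m1^2))
  expect_lt(abs(sim$total_delay - exact$total_delay), 3 * se)
  # zero-risk curve yields zero delay
  expect_equal(simulate_total_delay(zero_risk_curve(), s, 500, seed = 1)$total_delay, 0)
})

test_that("adding a visit never increases the total delay", {
  cv <- profile_curve(fx_profiles_nocens()[["IV"]])
  set.seed(502)
  for (i in 1:40) {
    base_months <- sort(sample(60, sample(1:15, 1)))
    extra <- sample(setdiff(1:60, base_months), 1)
    d0 <- expected_total_delay(cv, surveillance_schedule("a", base_months))$total_delay
    d1 <- expected_total_delay(cv, surveillance_schedule("b", c(base_months, extra)))$total_delay
    expect_lte(d1, d0)
  }
})

test_that("delay falls steeply as the visit budget grows", {
  # The own-mass threshold makes the exact schedule shift discontinuously
  # with the budget, so total delay is not strictly monotone in V; the
  # trend, however, must be strongly decreasing, monthly surveillance must
  # detect everything, and doubling the budget across the explored range
  # must at least halve the delay.
  cv <- profile_curve(fx_profiles_nocens()[["III"]])
  tab <- compare_strategies(cv, budgets = c(5:27, 60))
  rb <- tab[grepl("risk_based", tab$strategy), ]
  rb <- rb[order(rb$budget), ]
  expect_equal(rb$total_delay_months[rb$budget == 60], 0)
  expect_lt(stats::cor(rb$budget, rb$total_delay_months, method = "spearman"),
            -0.9)
  d <- setNames(rb$total_delay_months, rb$budget)
  expect_lt(d[["10"]], d[["5"]] / 2)
  expect_lt(d[["20"]], d[["10"]])
  expect_lt(d[["27"]], d[["14"]] / 2)
})

test_that("risk-based placement dominates periodic spacing on concentrated risk", {
  # Unimodal failure mass confined to the first year, scored on a 12-month
  # toy horizon (sentinel at month 13). The accumulation rule is a coverage
  # heuristic, not a delay optimizer, so it does not beat even spacing in
  # every single configuration; it must, however, win in the clear majority
  # of random configurations and by a solid margin on average.
  set.seed(503)
  gaps <- c()
  for (i in 1:100) {
    w <- stats::dlnorm(1:12, log(stats::runif(1, 3, 10)), stats::runif(1, 0.3, 0.9))
    p <- c(w / sum(w), rep(0, 48)) * 0.8
    cv <- monthly_risk_curve(c(0, cumsum(p)), "II", estimator = "bump")
    for (V in 1:6) {
      risk <- allocate_visits(p, V)$schedule
      periodic <- surveillance_schedule("periodic",
                                        round(seq(12 / V, 12, length.out = V)))
      gaps <- c(gaps,
                expected_total_delay(cv, risk, sentinel = 13)$total_delay -
                  expected_total_delay(cv, periodic, sentinel = 13)$total_delay)
    }
  }
  expect_gt(mean(gaps <= 1e-9), 0.7)   # wins or ties in most configurations
  expect_lt(mean(gaps), 0)             # and clearly on average
})

test_that("exhaustive small-horizon optimum lower-bounds the allocator", {
  # failures confined to a year; every possible schedule enumerated
  cv <- uniform12_curve()
  p <- monthly_probability(cv)
  for (V in 1:4) {
    combos <- utils::combn(12, V)
    best <- min(apply(combos, 2, function(ms) {
      expected_total_delay(cv, surveillance_schedule("x", ms))$total_delay
    }))
    got <- expected_total_delay(cv, allocate_visits(p, V)$schedule)$total_delay
    expect_gte(got, best - 1e-9)
  }
})
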