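test_that("guideline control schedules carry their published visit totals and phases", {
  most <- control_schedule("nccn_most")
  expect_equal(most$V, 27)
  expect_equal(most$visit_months,
               c(1:12, seq(14, 24, 2), seq(28, 60, 4)))
  mod <- control_schedule("nccn_moderate")
  expect_equal(mod$V, 15)
  expect_equal(mod$visit_months, c(seq(2, 12, 2), seq(16, 24, 4), seq(30, 60, 6)))
  least <- control_schedule("nccn_least")
  expect_equal(least$V, 10)
  expect_equal(least$visit_months, c(seq(3, 12, 3), c(18, 24), seq(32, 56, 8)))
  rtog <- control_schedule("rtog")
  expect_equal(rtog$V, 14)
  expect_equal(rtog$visit_months[1], 3)
  expect_equal(max(rtog$visit_months), 60)
  expect_error(control_schedule("nccn"), "nccn_most")
})

test_that("the accumulation rule reproduces hand-traced allocations", {
  # all mass in one month
  p <- rep(0, 60); p[15] <- 1
  expect_equal(allocate_visits(p, 1)$schedule$visit_months, 15L)

  # uniform risk, 5 visits: a[m] = 1/12 accrues to 1 every 12 months
  pu <- rep(1 / 60, 60)
  expect_equal(allocate_visits(pu, 5)$schedule$visit_months,
               as.integer(seq(12, 60, 12)))

  # uniform risk, 30 visits: a[m] = 0.5 < 0.7, visit every second month
  expect_equal(allocate_visits(pu, 30)$schedule$visit_months,
               as.integer(seq(2, 60, 2)))

  # two-point mass, both months above the threshold, excess carried safely
  p2 <- rep(0, 60); p2[10] <- 0.4; p2[20] <- 0.6
  expect_equal(allocate_visits(p2, 2)$schedule$visit_months, c(10L, 20L))
})

test_that("allocation degenerate inputs are rejected", {
  expect_error(allocate_visits(rep(0, 60), 5), "positive sum")
  expect_error(allocate_visits(rep(1 / 60, 60), 61), "infeasible")
  expect_error(allocate_visits(rep(1 / 60, 60), 0), "at least 1")
  expect_error(allocate_visits(rep(1 / 60, 30), 5), "length 60")
})

test_that("allocation conserves the budget and is scale invariant", {
  set.seed(401)
  for (i in 1:60) {
    p <- stats::runif(60)^3          # spiky, occasionally near-zero months
    p[sample(60, 10)] <- 0
    if (sum(p) == 0) p[1] <- 1
    V <- sample(1:60, 1)
    res <- allocate_visits(p, V)
    expect_equal(res$schedule$V, V)
    expect_equal(length(unique(res$schedule$visit_months)), V)
    expect_equal(sum(res$trace$a), V, tolerance = 1e-9)
    # any positive rescaling of p yields the identical schedule
    res2 <- allocate_visits(p * stats::runif(1, 0.01, 100), V)
    expect_identical(res2$schedule$visit_months, res$schedule$visit_months)
  }
})

test_that("for unimodal risk the visits concentrate where the mass is", {
  set.seed(402)
  for (i in 1:25) {
    med <- stats::runif(1, 10, 40)
    p <- stats::dlnorm(1:60, log(med), stats::runif(1, 0.3, 0.8))
    V <- sample(5:27, 1)
    s <- allocate_visits(p, V)$schedule
    cum <- cumsum(p) / sum(p)
    q25 <- which(cum >= 0.25)[1]; q75 <- which(cum >= 0.75)[1]
    expect_true(stats::median(s$visit_months) >= q25)
    expect_true(stats::median(s$visit_months) <= q75)
  }
})

# Literal re-implementation of the allocation rules as an independent oracle,
# readable straight off the prose: proportional assignment, 0.7 own-mass
# rule, accrual to 1, reset with capped carry, then exact-budget repair.
# Comparisons carry the same 1e-9 exact-arithmetic tolerance as the
# implementation (accrued mass that sums to 1 exactly, e.g. uniform risk
# over a year, must trigger a visit regardless of double rounding).
allocate_oracle <- function(p, V, threshold = 0.7) {
  a <- V * p / sum(p)
  sched <- c()
  A <- 0
  for (m in 1:60) {
    A <- A + a[m]
    visit <- FALSE
    if (a[m] >= threshold - 1e-9) visit <- TRUE
    if (A >= 1 - 1e-9) visit <- TRUE
    if (visit) {
      sched <- c(sched, m)
      A <- A - 1
      if (A < 0) A <- 0
      if (A > 1 - 1e-6) A <- 1 - 1e-6
    }
  }
  while (length(sched) < V) {
    rest <- setdiff(1:60, sched)
    best <- rest[order(-round(a[rest], 9), rest)][1]
    sched <- sort(c(sched, best))
  }
  while (length(sched) > V) {
    worst <- sched[order(round(a[sched], 9), -sched)][1]
    sched <- setdiff(sched, worst)
  }
  sort(sched)
}

test_that("the sweep matches the literal oracle on 12-month toy horizons", {
  set.seed(403)
  for (i in 1:100) {
    p <- rep(0, 60)
    p[1:12] <- stats::runif(12)^2
    if (sum(p) == 0) p[3] <- 1
    V <- sample(1:6, 1)
    expect_equal(allocate_visits(p, V)$schedule$visit_months,
                 as.integer(allocate_oracle(p, V)))
  }
})

test_that("yearly visit counts follow the year-boundary convention", {
  s <- surveillance_schedule("fig3", c(7, 8, 10, 12, 14, 16, 19, 23, 27, 30, 36, 44, 52))
  expect_equal(yearly_counts(s), c(4L, 4L, 3L, 1L, 1L))
  expect_equal(yearly_counts(surveillance_schedule("none", integer(0))),
               rep(0L, 5))
  expect_equal(yearly_counts(surveillance_schedule("bounds", seq(12, 60, 12))),
               rep(1L, 5))
  expect_equal(sum(yearly_counts(control_schedule("nccn_most"))), 27)
})

test_that("schedules survive a JSON round trip", {
  scheds <- list(control_schedule("rtog"),
                 surveillance_schedule("custom", c(5, 17, 42)))
  path <- withr::local_tempfile(fileext = ".json")
  write_schedules(scheds, path)
  back <- read_schedules(path)
  expect_equal(length(back), 2)
  for (i in 1:2) {
    expect_identical(back[[i]]$name, scheds[[i]]$name)
    expect_identical(back[[i]]$visit_months, scheds[[i]]$visit_months)
  }
})
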