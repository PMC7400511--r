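#' Delayed-detection time of a failure under a schedule
#'
#' Months from failure occurrence to the next scheduled visit at or after the
#' failure month: a patient failing in month 6 whose next planned visit is
#' month 9 is detected 3 months late; a visit in the failure month itself
#' detects with no delay. Failures after the last visit are detected at the
#' horizon sentinel (month 61 by default), so schedules that stop early are
#' not rewarded.
#'
#' @param failure_month integer vector of failure months in 1..60.
#' @param schedule a [surveillance_schedule()].
#' @param sentinel detection month applied to failures after the final visit;
#'   default 61 (one month past the horizon).
#' @return integer vector of delays in months.
#' @examples
#' s <- surveillance_schedule("toy", c(3, 9, 12))
#' detection_delay(6, s)   # 3
#' @export
detection_delay <- function(failure_month, schedule, sentinel = 61L) {
  stopifnot(inherits(schedule, "surveillance_schedule"))
  fm <- as.integer(failure_month)
  if (any(is.na(fm)) || any(fm < 1) || any(fm > 60)) {
    stop("failure_month must lie in 1..60")
  }
  visits <- schedule$visit_months
  nxt <- vapply(fm, function(m) {
    hit <- visits[visits >= m]
    # failures past the final visit are picked up at the sentinel; a failure
    # already beyond the sentinel is detected there and then (zero delay)
    if (length(hit)) hit[1] else max(as.integer(sentinel), m)
  }, integer(1))
  nxt - fm
}

delay_report <- function(strategy, n, total_delay, failure_mass, curve) {
  structure(list(strategy = strategy, n = n, total_delay = total_delay,
                 expected_delay_per_failure =
                   if (failure_mass > 0) total_delay / (n * failure_mass) else 0,
                 failure_mass = failure_mass,
                 curve = sprintf("%s/%s [%s]", curve$group, curve$endpoint, curve$estimator)),
            class = "delay_report")
}

#' @export
print.delay_report <- function(x, ...) {
  cat("<delay_report>", x$strategy, "on", x$curve, "\n")
  cat(sprintf("  cohort n=%d, total delay %.1f months (%.2f per failure)\n",
              x$n, x$total_delay, x$expected_delay_per_failure))
  invisible(x)
}

#' Expected total delayed-detection months in a hypothetical cohort
#'
#' Exact expectation of the summed delayed-detection months over a
#' hypothetical cohort of `n` patients whose failure months are distributed
#' according to the curve's monthly probabilities:
#' `n * sum_m p[m] * delay(m, schedule)`. Patients without failure
#' contribute zero.
#'
#' @param curve a [monthly_risk_curve()].
#' @param schedule a [surveillance_schedule()].
#' @param n hypothetical cohort size (default 1000).
#' @param sentinel passed to [detection_delay()].
#' @return a `delay_report` with `total_delay` (months) and
#'   `expected_delay_per_failure`.
#' @export
expected_total_delay <- function(curve, schedule, n = 1000L, sentinel = 61L) {
  stopifnot(inherits(curve, "monthly_risk_curve"), n >= 1)
  act <- which(curve$p > 0)
  total <- if (length(act)) {
    n * sum(curve$p[act] * detection_delay(act, schedule, sentinel))
  } else 0
  delay_report(schedule$name, as.integer(n), total, sum(curve$p), curve)
}

#' Simulated total delayed-detection months
#'
#' Stochastic twin of [expected_total_delay()]: draws each patient's failure
#' month (or no failure) from the curve's monthly probabilities and sums the
#' realized delays. Deterministic given the seed.
#'
#' @inheritParams expected_total_delay
#' @param seed integer seed.
#' @export
simulate_total_delay <- function(curve, schedule, n = 1000L, seed = 1L, sentinel = 61L) {
  stopifnot(inherits(curve, "monthly_risk_curve"), n >= 1)
  set.seed(as.integer(seed))
  prob <- c(curve$p, 1 - sum(curve$p))  # month 1..60 or no failure
  draw <- sample.int(61, size = n, replace = TRUE, prob = prob)
  fm <- draw[draw <= 60]
  total <- if (length(fm)) sum(detection_delay(fm, schedule, sentinel)) else 0
  delay_report(schedule$name, as.integer(n), total, sum(curve$p), curve)
}

#' Compare risk-based and control strategies across visit budgets
#'
#' Builds a risk-based schedule for every budget in `budgets` via
#' [allocate_visits()], scores it and the control strategies by expected
#' total delayed-detection months over a hypothetical cohort, and tabulates
#' the result.
#'
#' @param curve a [monthly_risk_curve()] for the group under study.
#' @param budgets integer vector of visit budgets for risk-based schedules
#'   (default 5..27).
#' @param controls character vector of control strategy names.
#' @param n hypothetical cohort size.
#' @param threshold allocation threshold, see [allocate_visits()].
#' @param smoothing_window passed to [monthly_probability()].
#' @return data frame with columns `group,strategy,budget,total_delay_months,
#'   expected_delay_per_failure`.
#' @export
compare_strategies <- function(curve, budgets = 5:27,
                               controls = control_names(), n = 1000L,
                               threshold = 0.7, smoothing_window = 1L) {
  stopifnot(inherits(curve, "monthly_risk_curve"))
  p <- monthly_probability(curve, smoothing_window)
  if (sum(p) <= 0) {
    # a flat curve carries no scheduling signal: fall back to uniform risk
    p <- rep(1 / 60, 60)
  }
  score <- function(s, budget) {
    rep_ <- expected_total_delay(curve, s, n)
    data.frame(group = curve$group, strategy = s$name, budget = budget,
               total_delay_months = rep_$total_delay,
               expected_delay_per_failure = rep_$expected_delay_per_failure,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(budgets, function(V) {
    score(allocate_visits(p, V, threshold)$schedule, V)
  })
  rows <- c(rows, lapply(controls, function(nm) {
    s <- control_schedule(nm)
    score(s, s$V)
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
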