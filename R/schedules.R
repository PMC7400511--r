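#' Surveillance schedules
#'
#' A `surveillance_schedule` is a named, strictly increasing set of visit
#' months within the 60-month (5-year) post-treatment horizon, at most one
#' visit per month. Its budget `V` is the number of visits.
#'
#' @param name strategy name.
#' @param visit_months integer vector of distinct months in 1..60.
#' @return object of class `surveillance_schedule` with elements `name`,
#'   `visit_months` (sorted) and `V`.
#' @export
surveillance_schedule <- function(name, visit_months) {
  m <- as.integer(visit_months)
  if (length(m) && (any(is.na(m)) || any(m < 1) || any(m > 60))) {
    stop("visit months must lie in 1..60")
  }
  if (anyDuplicated(m)) stop("at most one visit per month")
  m <- sort(m)
  structure(list(name = as.character(name), visit_months = m, V = length(m)),
            class = "surveillance_schedule")
}

#' @export
print.surveillance_schedule <- function(x, ...) {
  cat("<surveillance_schedule>", x$name, "-", x$V, "visits\n")
  cat("  months:", paste(x$visit_months, collapse = " "), "\n")
  cat("  by year:", paste(yearly_counts(x), collapse = "/"), "\n")
  invisible(x)
}

#' Guideline control schedules
#'
#' The four control strategies:
#' * `nccn_most`: monthly in year 1, every 2 months in year 2, every 4 months
#'   in years 3-5 (27 visits);
#' * `nccn_moderate`: every 2 months in year 1, every 4 months in year 2,
#'   every 6 months in years 3-5 (15 visits);
#' * `nccn_least`: every 3 months in year 1, every 6 months in year 2, every
#'   8 months in years 3-5 (10 visits);
#' * `rtog`: every 3 months in years 1-2, every 6 months in years 3-5
#'   (14 visits).
#'
#' "Every k months" anchors visits at k, 2k, ... from the start of each
#' phase (year 1, year 2, years 3-5).
#'
#' @param name one of `"nccn_most"`, `"nccn_moderate"`, `"nccn_least"`,
#'   `"rtog"`.
#' @return a [surveillance_schedule()].
#' @examples
#' control_schedule("nccn_most")$V   # 27
#' control_schedule("rtog")$V        # 14
#' @export
control_schedule <- function(name) {
  phased <- function(phases) {
    unlist(lapply(phases, function(ph) seq(ph$start - 1 + ph$k, ph$end, by = ph$k)))
  }
  months <- switch(name,
    nccn_most = phased(list(list(start = 1, end = 12, k = 1),
                            list(start = 13, end = 24, k = 2),
                            list(start = 25, end = 60, k = 4))),
    nccn_moderate = phased(list(list(start = 1, end = 12, k = 2),
                                list(start = 13, end = 24, k = 4),
                                list(start = 25, end = 60, k = 6))),
    nccn_least = phased(list(list(start = 1, end = 12, k = 3),
                             list(start = 13, end = 24, k = 6),
                             list(start = 25, end = 60, k = 8))),
    rtog = phased(list(list(start = 1, end = 24, k = 3),
                       list(start = 25, end = 60, k = 6))),
    stop("unknown control strategy '", name,
         "'; valid names: nccn_most, nccn_moderate, nccn_least, rtog")
  )
  surveillance_schedule(name, months)
}

control_names <- function() c("nccn_most", "nccn_moderate", "nccn_least", "rtog")

#' Allocate a budget of visits to months by recurrence risk
#'
#' Distributes `V` follow-up visits over months 1..60 in proportion to the
#' monthly recurrence probability `p`. The raw allocation is
#' `a[m] = V * p[m] / sum(p)` follow-ups per month. Months are swept in
#' order with an accumulator `A`:
#' * `A` gains `a[m]`;
#' * a visit is scheduled at `m` when `a[m] >= threshold` (enough risk in the
#'   month itself) or when `A >= 1` (accrued risk from visit-free months);
#' * after a visit, `A` drops by 1 (never below 0) and any carried excess is
#'   capped below 1 so that carry-over alone never forces back-to-back
#'   visits - excess mass instead supports later high-risk months.
#'
#' The sweep alone cannot guarantee exactly `V` visits, so a repair step
#' enforces the budget: missing visits are added at unscheduled months in
#' decreasing order of `a[m]` (ties to the earlier month, favouring earlier
#' detection); surplus visits are removed at scheduled months in increasing
#' order of `a[m]` (ties to the later month).
#'
#' @param p numeric vector of length 60 of non-negative monthly event
#'   probabilities with positive sum (any positive scaling of `p` yields the
#'   same schedule).
#' @param V integer visit budget, 1..60.
#' @param threshold per-month allocation above which a month gets its own
#'   visit; default 0.7.
#' @param name name for the resulting schedule.
#' @return list with elements `schedule` (a [surveillance_schedule()]) and
#'   `trace` (a data frame with per-month allocation `a`, accumulator after
#'   the month, and the scheduling decision).
#' @examples
#' p <- rep(1 / 60, 60)
#' allocate_visits(p, V = 5)$schedule$visit_months   # 12 24 36 48 60
#' @export
allocate_visits <- function(p, V, threshold = 0.7, name = sprintf("risk_based_%d", V)) {
  if (!is.numeric(p) || length(p) != 60 || any(!is.finite(p)) || any(p < 0)) {
    stop("p must be a non-negative numeric vector of length 60")
  }
  if (sum(p) <= 0) stop("p must have positive sum")
  V <- as.integer(V)
  if (V < 1) stop("V must be at least 1")
  if (V > 60) stop("infeasible budget: at most one visit per month allows V <= 60")

  a <- V * p / sum(p)
  # decision tolerance: comparisons and repair ordering must not depend on
  # the last-ulp representation of p (scale invariance)
  eps <- 1e-9
  A <- 0
  scheduled <- logical(60)
  A_after <- numeric(60)
  action <- character(60)
  for (m in 1:60) {
    A <- A + a[m]
    if (a[m] >= threshold - eps || A >= 1 - eps) {
      scheduled[m] <- TRUE
      action[m] <- if (a[m] >= threshold - eps) "own-mass visit" else "accrued visit"
      A <- max(A - 1, 0)
      A <- min(A, 1 - 1e-6)   # carried excess may support, not force, later visits
    } else {
      action[m] <- "accrue"
    }
    A_after[m] <- A
  }

  n_sched <- sum(scheduled)
  a_ord <- round(a, 9)
  if (n_sched < V) {
    cand <- which(!scheduled)
    cand <- cand[order(-a_ord[cand], cand)]
    add <- cand[seq_len(V - n_sched)]
    scheduled[add] <- TRUE
    action[add] <- "repair add"
  } else if (n_sched > V) {
    cand <- which(scheduled)
    cand <- cand[order(a_ord[cand], -cand)]
    drop <- cand[seq_len(n_sched - V)]
    scheduled[drop] <- FALSE
    action[drop] <- "repair remove"
  }

  trace <- data.frame(month = 1:60, a = a, accumulator = A_after,
                      scheduled = scheduled, action = action,
                      stringsAsFactors = FALSE)
  list(schedule = surveillance_schedule(name, which(scheduled)), trace = trace)
}

#' Visits per follow-up year
#'
#' Counts visits in years 1-5 (months 1-12, 13-24, 25-36, 37-48, 49-60).
#'
#' @param schedule a [surveillance_schedule()].
#' @return integer vector of length 5 summing to the budget.
#' @export
yearly_counts <- function(schedule) {
  stopifnot(inherits(schedule, "surveillance_schedule"))
  yr <- cut(schedule$visit_months, breaks = c(0, 12, 24, 36, 48, 60), labels = FALSE)
  as.integer(tabulate(yr, nbins = 5))
}

#' Write / read schedules as JSON
#'
#' @param schedules a `surveillance_schedule` or list of them.
#' @param path file path.
#' @export
write_schedules <- function(schedules, path) {
  if (inherits(schedules, "surveillance_schedule")) schedules <- list(schedules)
  out <- lapply(schedules, function(s) list(name = s$name, months = s$visit_months))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedules
#' @export
read_schedules <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i) {
    surveillance_schedule(raw$name[i], unlist(raw$months[i]))
  })
}
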