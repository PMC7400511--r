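#' Markov cohort model specification
#'
#' Six health states: no evidence of disease (`NED`), early-stage recurrence,
#' advanced-stage recurrence, salvage treatment, no evidence of disease after
#' salvage, and death (absorbing). Cycles last one month. Utilities are QALY
#' weights per year, accrued as weight/12 per cycle at cycle start (no
#' half-cycle correction); costs are per cycle of state occupancy plus a per
#' visit surveillance cost charged to the at-risk states (`NED`,
#' `NED_after_salvage`). The recurrence-onset hazard during months 1-60 comes
#' from a [monthly_risk_curve()]; beyond the surveillance horizon a small
#' constant tail hazard applies. A recurrence is classified early-stage when
#' the schedule detects it within `early_window_months` of onset, advanced
#' otherwise.
#'
#' The default parameter file shipped with the package
#' (`markov_params_synthetic.yaml`) contains synthetic placeholder values in
#' plausible clinical ranges; absolute costs and QALYs computed from it are
#' illustrative only.
#'
#' @param params a list of parameters, or a path to a YAML file with entries
#'   `utilities`, `costs_monthly`, `visit_cost`, `transitions`,
#'   `tail_hazard_monthly`, `early_window_months`, `discount_annual`,
#'   `horizon_cycles`. Default: the shipped synthetic baseline.
#' @return object of class `markov_spec`.
#' @export
markov_spec <- function(params = NULL) {
  if (is.null(params)) {
    params <- system.file("extdata", "markov_params_synthetic.yaml",
                          package = "riskvisit", mustWork = TRUE)
  }
  if (is.character(params)) params <- yaml::read_yaml(params)
  states <- markov_states()
  u <- unlist(params$utilities)[states]
  cm <- unlist(params$costs_monthly)[states]
  if (any(is.na(u)) || any(u < 0) || any(u > 1)) {
    stop("utilities must be given for every state and lie in [0, 1]")
  }
  if (any(is.na(cm)) || any(cm < 0)) stop("costs_monthly must be non-negative for every state")
  if (params$visit_cost < 0) stop("visit_cost must be non-negative")
  tr <- params$transitions
  for (pair in list(c("er_to_salvage", "er_death"),
                    c("ar_to_salvage", "ar_death"),
                    c("salvage_to_ned", "salvage_death"))) {
    s <- sum(unlist(tr[pair]))
    if (s > 1) stop("outgoing transition probabilities exceed 1 for state feeding ", pair[1])
  }
  structure(list(utilities = u, costs_monthly = cm,
                 visit_cost = params$visit_cost, transitions = tr,
                 tail_hazard = params$tail_hazard_monthly,
                 early_window = params$early_window_months,
                 discount_annual = params$discount_annual,
                 horizon = as.integer(params$horizon_cycles),
                 label = params$label %||% "unlabelled"),
            class = "markov_spec")
}

markov_states <- function() {
  c("NED", "early_recurrence", "advanced_recurrence",
    "salvage_treatment", "NED_after_salvage", "death")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.markov_spec <- function(x, ...) {
  cat("<markov_spec>", x$label, "-", x$horizon, "monthly cycles,",
      sprintf("discount %.1f%%/yr, early window %d mo\n",
              100 * x$discount_annual, x$early_window))
  invisible(x)
}

#' Propagate a cohort through the Markov model under one schedule
#'
#' Deterministic occupancy propagation (no sampling). Each cycle accrues
#' discounted utilities and state costs at cycle start, charges the visit
#' cost at scheduled visit months to the at-risk occupancy, then applies the
#' transition matrix. Occupancy conservation is asserted every cycle.
#'
#' @param spec a [markov_spec()].
#' @param schedule a [surveillance_schedule()].
#' @param curve a [monthly_risk_curve()] supplying the recurrence-onset
#'   hazard during months 1-60.
#' @return list with `cost` ($), `qalys`, and `trace` (cycle x state
#'   occupancy matrix).
#' @export
run_markov <- function(spec, schedule, curve) {
  stopifnot(inherits(spec, "markov_spec"),
            inherits(schedule, "surveillance_schedule"),
            inherits(curve, "monthly_risk_curve"))
  states <- markov_states()
  ns <- length(states)
  tr <- spec$transitions

  # conditional monthly onset hazard from the cumulative curve
  Fv <- curve$F
  onset60 <- vapply(1:60, function(m) {
    at_risk <- 1 - Fv[m]
    if (at_risk <= 0) 0 else min(curve$p[m] / at_risk, 0.999999)
  }, numeric(1))

  delays <- detection_delay(1:60, schedule)
  early60 <- delays <= spec$early_window

  occ <- c(1, rep(0, ns - 1))
  names(occ) <- states
  trace <- matrix(NA_real_, nrow = spec$horizon, ncol = ns,
                  dimnames = list(NULL, states))
  cost <- 0; qalys <- 0
  monthly_rate <- (1 + spec$discount_annual)^(1 / 12) - 1

  for (t in seq_len(spec$horizon)) {
    disc <- 1 / (1 + monthly_rate)^(t - 1)
    qalys <- qalys + disc * sum(occ * spec$utilities) / 12
    cost <- cost + disc * sum(occ * spec$costs_monthly)
    if (t <= 60 && t %in% schedule$visit_months) {
      cost <- cost + disc * spec$visit_cost * (occ["NED"] + occ["NED_after_salvage"])
    }

    onset <- if (t <= 60) onset60[t] else spec$tail_hazard
    early <- if (t <= 60) early60[t] else FALSE

    P <- matrix(0, ns, ns, dimnames = list(states, states))
    P["NED", "death"] <- tr$ned_death
    P["NED", "early_recurrence"] <- (1 - tr$ned_death) * onset * as.numeric(early)
    P["NED", "advanced_recurrence"] <- (1 - tr$ned_death) * onset * as.numeric(!early)
    P["NED", "NED"] <- 1 - sum(P["NED", -1])
    P["early_recurrence", "salvage_treatment"] <- tr$er_to_salvage
    P["early_recurrence", "death"] <- tr$er_death
    P["early_recurrence", "early_recurrence"] <- 1 - tr$er_to_salvage - tr$er_death
    P["advanced_recurrence", "salvage_treatment"] <- tr$ar_to_salvage
    P["advanced_recurrence", "death"] <- tr$ar_death
    P["advanced_recurrence", "advanced_recurrence"] <- 1 - tr$ar_to_salvage - tr$ar_death
    P["salvage_treatment", "NED_after_salvage"] <- tr$salvage_to_ned
    P["salvage_treatment", "death"] <- tr$salvage_death
    P["salvage_treatment", "salvage_treatment"] <- 1 - tr$salvage_to_ned - tr$salvage_death
    P["NED_after_salvage", "death"] <- tr$neds_death
    P["NED_after_salvage", "NED_after_salvage"] <- 1 - tr$neds_death
    P["death", "death"] <- 1

    bad <- which(abs(rowSums(P) - 1) > 1e-12 | apply(P, 1, min) < -1e-15)
    if (length(bad)) {
      stop("transition row does not sum to 1 for state(s): ",
           paste(states[bad], collapse = ", "))
    }

    occ <- drop(occ %*% P)
    if (abs(sum(occ) - 1) > 1e-12) stop("occupancy not conserved at cycle ", t)
    trace[t, ] <- occ
  }
  list(cost = cost, qalys = qalys, trace = trace)
}

#' Incremental cost-effectiveness ratio
#'
#' Incremental cost and effectiveness of a strategy against a reference, and
#' their ratio. The reported ICER is rounded to the nearest dollar. When the
#' incremental effectiveness is not positive no division is performed: the
#' result is flagged `"dominated"` (strategy costs at least as much for no
#' QALY gain) or `"undefined"` (no difference at all).
#'
#' @param cost_s,qaly_s cost ($) and effectiveness (QALYs) of the strategy.
#' @param cost_ref,qaly_ref cost and effectiveness of the reference strategy.
#' @return list with `incremental_cost`, `incremental_effectiveness`, `icer`
#'   (NA when not defined) and `status` (`"ok"`, `"dominated"`,
#'   `"undefined"`).
#' @examples
#' compute_icer(11138, 36.734, 9187, 36.049)$icer   # 2848
#' @export
compute_icer <- function(cost_s, qaly_s, cost_ref, qaly_ref) {
  stopifnot(is.finite(cost_s), is.finite(qaly_s), is.finite(cost_ref), is.finite(qaly_ref))
  dc <- cost_s - cost_ref
  de <- qaly_s - qaly_ref
  if (de > 0) {
    list(incremental_cost = dc, incremental_effectiveness = de,
         icer = round(dc / de), status = "ok")
  } else if (dc == 0 && de == 0) {
    list(incremental_cost = 0, incremental_effectiveness = 0,
         icer = NA_real_, status = "undefined")
  } else {
    list(incremental_cost = dc, incremental_effectiveness = de,
         icer = NA_real_, status = "dominated")
  }
}

#' Cost-effectiveness table for a set of strategies
#'
#' Runs the Markov model for every strategy and reports costs, QALYs and
#' incremental values against the reference strategy (by default the least
#' intensive NCCN schedule, whose row carries zero incrementals).
#'
#' @param spec a [markov_spec()].
#' @param strategies named list of [surveillance_schedule()] objects; must
#'   contain `reference`.
#' @param curve the group's [monthly_risk_curve()].
#' @param reference name of the reference strategy.
#' @return data frame with columns `strategy, cost, incremental_cost,
#'   effectiveness, incremental_effectiveness, icer, status`.
#' @export
cea_table <- function(spec, strategies, curve, reference = "nccn_least") {
  if (inherits(strategies, "surveillance_schedule")) {
    strategies <- setNames(list(strategies), strategies$name)
  }
  if (is.null(names(strategies))) {
    names(strategies) <- vapply(strategies, `[[`, character(1), "name")
  }
  runs <- lapply(strategies, run_markov, spec = spec, curve = curve)
  single <- length(strategies) == 1
  if (!single && !reference %in% names(strategies)) {
    stop("reference strategy '", reference, "' not among the strategies")
  }
  ref <- if (single) runs[[1]] else runs[[reference]]
  rows <- lapply(names(strategies), function(nm) {
    r <- runs[[nm]]
    ic <- compute_icer(r$cost, r$qalys, ref$cost, ref$qalys)
    data.frame(strategy = nm, cost = r$cost,
               incremental_cost = ic$incremental_cost,
               effectiveness = r$qalys,
               incremental_effectiveness = ic$incremental_effectiveness,
               icer = ic$icer,
               status = if (nm == (if (single) nm else reference)) "reference" else ic$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # reference row: zero incrementals by definition
  refrow <- if (single) 1 else which(out$strategy == reference)
  out$incremental_cost[refrow] <- 0
  out$incremental_effectiveness[refrow] <- 0
  out$icer[refrow] <- NA_real_
  out
}
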