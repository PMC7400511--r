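#' Monthly risk curves
#'
#' A `monthly_risk_curve` stores cumulative event probability `F` at months
#' 0..60 for one group and endpoint, together with the implied monthly event
#' probabilities `p[m] = F[m] - F[m-1]`. Invariants: `F[0] = 0`, `F`
#' non-decreasing, `F[60] <= 1`, `p >= 0`, and `sum(p) == F[60]` exactly.
#'
#' @param F numeric vector of length 61 (months 0..60) of cumulative event
#'   probabilities.
#' @param group group label.
#' @param endpoint endpoint label (`"DF"`, `"DM"`, `"LR"`, `"RR"`).
#' @param estimator free-text tag recording the estimator and its settings.
#' @return object of class `monthly_risk_curve` with elements `F` (length 61),
#'   `p` (length 60), `group`, `endpoint`, `estimator`.
#' @export
monthly_risk_curve <- function(F, group, endpoint = "DF", estimator = "unspecified") {
  if (!is.numeric(F) || length(F) != 61 || any(!is.finite(F))) {
    stop("F must be a finite numeric vector of length 61 (months 0..60)")
  }
  if (abs(F[1]) > 1e-12) stop("F[0] must be 0")
  F[1] <- 0
  if (any(diff(F) < -1e-9)) stop("F must be non-decreasing")
  F <- cummax(pmin(F, 1))
  structure(list(F = F, p = diff(F), group = group, endpoint = endpoint,
                 estimator = estimator),
            class = "monthly_risk_curve")
}

#' @export
print.monthly_risk_curve <- function(x, ...) {
  cat("<monthly_risk_curve> group", x$group, "endpoint", x$endpoint,
      "[", x$estimator, "]\n")
  cat(sprintf("  F(12)=%.3f F(24)=%.3f F(36)=%.3f F(60)=%.3f; peak month %d\n",
              x$F[13], x$F[25], x$F[37], x$F[61], which.max(x$p)))
  invisible(x)
}

#' @export
plot.monthly_risk_curve <- function(x, ...) {
  graphics::plot(0:60, x$F, type = "s", xlab = "month since end of treatment",
                 ylab = "cumulative event probability",
                 main = sprintf("group %s, %s", x$group, x$endpoint), ...)
  invisible(x)
}

#' Kaplan-Meier monthly risk curves per group
#'
#' Product-limit estimate of the cumulative event probability `1 - S(t)`
#' for one endpoint, evaluated on the monthly grid, separately per risk
#' group. Serves as the nonparametric reference estimator; it shares its
#' return type with [fit_rsf_curves()] so downstream stages are
#' estimator-agnostic.
#'
#' @param cohort an `npc_cohort`.
#' @param endpoint endpoint label; competing failures censor non-`DF`
#'   endpoints (see [endpoint_times()]).
#' @return named list of `monthly_risk_curve`, one per group present in the
#'   cohort; groups with zero patients are absent (with a warning).
#' @export
fit_km_curves <- function(cohort, endpoint = "DF") {
  dat <- endpoint_times(cohort, endpoint)
  fit_by_group(dat, endpoint, function(d) {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = d)
    s <- summary(fit, times = 0:60, extend = TRUE)$surv
    1 - s
  }, estimator = "km")
}

fit_by_group <- function(dat, endpoint, fun, estimator) {
  present <- intersect(group_levels(), unique(dat$group))
  absent <- setdiff(unique(dat$group), group_levels())
  if (length(absent)) stop("unknown group label(s): ", paste(absent, collapse = ", "))
  empty <- setdiff(group_levels(), present)
  if (length(empty)) {
    warning("no patients in group(s) ", paste(empty, collapse = ", "),
            "; omitted from the curve set")
  }
  curves <- lapply(present, function(g) {
    d <- dat[dat$group == g, , drop = FALSE]
    monthly_risk_curve(fun(d), group = g, endpoint = endpoint, estimator = estimator)
  })
  names(curves) <- present
  curves
}

#' Random-survival-forest monthly risk curves per group
#'
#' Grows a forest of bootstrap survival trees with log-rank splitting on the
#' full cohort, risk-adjusting for the twelve baseline covariates (sex, age,
#' smoking, alcohol, family history, EBV DNA, HGB, ALB, CRP, LDH, T and N
#' category). Each tree is grown on a bootstrap sample (about 63% in-bag);
#' every patient's survival curve is predicted from the trees for which the
#' patient was out-of-bag, and the per-patient out-of-bag ensemble curves are
#' averaged within each risk group to give a risk-adjusted group curve.
#'
#' The default terminal node size is `max(15, ceiling(0.05 * n))`: group-curve
#' estimation needs terminal risk sets large enough that the within-node
#' Nelson-Aalen estimator stays calibrated; very small nodes (tuned for risk
#' discrimination) inflate the cumulative hazard when covariates carry little
#' signal.
#'
#' @inheritParams fit_km_curves
#' @param n_trees number of bootstrap survival trees (the reference setting
#'   is 1000; a few hundred suffice for group-level curves).
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param mtry covariates tried per split; default `ceiling(sqrt(12))`.
#' @param min_node_size minimum terminal node size; default
#'   `max(15, ceiling(0.05 * nrow(cohort)))`.
#' @return named list of `monthly_risk_curve` per group present.
#' @export
fit_rsf_curves <- function(cohort, endpoint = "DF", n_trees = 1000, seed = 1L,
                           mtry = NULL, min_node_size = NULL) {
  if (!is.numeric(n_trees) || n_trees < 1) stop("n_trees must be a positive integer")
  dat <- endpoint_times(cohort, endpoint)
  if (sum(dat$status) == 0) {
    # no events anywhere: the ensemble curve is identically zero (and the
    # forest backend cannot grow survival trees without a single death time)
    return(fit_by_group(dat, endpoint, function(d) rep(0, 61),
                        estimator = "rsf(no events)"))
  }
  covs <- c("sex", "age", "smoking", "alcohol", "family_history", "ebv_dna",
            "hgb", "alb", "crp", "ldh", "t_category", "n_category")
  x <- cohort[covs]
  x$sex <- factor(x$sex, levels = c("male", "female"))
  x$t_category <- factor(x$t_category, levels = paste0("T", 1:4))
  x$n_category <- factor(x$n_category, levels = paste0("N", 0:3))
  df <- cbind(dat[c("time", "status")], x)
  if (is.null(mtry)) mtry <- ceiling(sqrt(length(covs)))
  if (is.null(min_node_size)) min_node_size <- max(15, ceiling(0.05 * nrow(df)))

  fit <- ranger::ranger(survival::Surv(time, status) ~ ., data = df,
                        num.trees = as.integer(n_trees), splitrule = "logrank",
                        mtry = mtry, min.node.size = min_node_size,
                        seed = as.integer(seed), num.threads = 1)
  # out-of-bag per-patient survival, step-interpolated onto the monthly grid
  times <- fit$unique.death.times
  S <- fit$survival                              # n x length(times), OOB
  grid_idx <- vapply(0:60, function(m) {
    k <- which(times <= m)
    if (length(k)) max(k) else 0L
  }, integer(1))
  S_grid <- cbind(1, S)[, grid_idx + 1, drop = FALSE]  # S(0) = 1

  est <- sprintf("rsf(trees=%d,mtry=%d,min_node=%d,seed=%d)",
                 as.integer(n_trees), mtry, min_node_size, as.integer(seed))
  dat$row <- seq_len(nrow(dat))
  fit_by_group(dat, endpoint, function(d) {
    Fm <- 1 - colMeans(S_grid[d$row, , drop = FALSE])
    Fm[1] <- 0
    cummax(Fm)
  }, estimator = est)
}

#' Time-specific monthly event probabilities from a risk curve
#'
#' First differences of the cumulative curve, optionally smoothed by a
#' centered moving average with edge truncation (the window shrinks at the
#' ends of the grid). After smoothing, the vector is rescaled so its sum
#' equals `F[60]` exactly: the total five-year event mass is conserved.
#'
#' @param curve a [monthly_risk_curve()].
#' @param smoothing_window odd positive integer; `1` (default) returns the raw
#'   first differences.
#' @return numeric vector of length 60 of monthly event probabilities.
#' @export
monthly_probability <- function(curve, smoothing_window = 1L) {
  stopifnot(inherits(curve, "monthly_risk_curve"))
  w <- as.integer(smoothing_window)
  if (w < 1 || w %% 2 == 0) stop("smoothing_window must be a positive odd integer")
  p <- curve$p
  if (w == 1) return(p)
  half <- (w - 1) / 2
  sm <- vapply(seq_along(p), function(m) {
    lo <- max(1, m - half); hi <- min(length(p), m + half)
    mean(p[lo:hi])
  }, numeric(1))
  total <- curve$F[61]
  if (sum(sm) > 0) sm <- sm * (total / sum(sm))
  sm
}

#' Write / read sets of monthly risk curves
#'
#' Long CSV with columns `group,endpoint,month,F,p,estimator`; month runs
#' 0..60 (`p` is empty at month 0).
#'
#' @param curves named list of `monthly_risk_curve`.
#' @param path file path.
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(group = cv$group, endpoint = cv$endpoint, month = 0:60,
               F = cv$F, p = c(NA, cv$p), estimator = cv$estimator,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "endpoint", "month", "F")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("curve file missing column(s): ", paste(missing, collapse = ", "))
  out <- lapply(split(df, df$group), function(d) {
    d <- d[order(d$month), ]
    monthly_risk_curve(d$F, group = d$group[1], endpoint = d$endpoint[1],
                       estimator = if ("estimator" %in% names(d)) d$estimator[1] else "file")
  })
  out[intersect(group_levels(), names(out))]
}
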