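#' Group-specific monthly hazard profiles
#'
#' A `group_hazard_profile` holds, for one risk group, per-month discrete
#' hazards on a 60-month grid for each recurrence endpoint (distant metastasis
#' `DM`, local recurrence `LR`, regional recurrence `RR`), a background death
#' hazard, and a monthly censoring hazard. Follow-up is administratively
#' censored at month 60. Disease failure (`DF`) is the composite first event
#' of DM, LR, RR or death.
#'
#' @name group_hazard_profile
NULL

endpoint_levels <- function() c("DF", "DM", "LR", "RR")
event_processes <- function() c("DM", "LR", "RR", "death")

#' Construct a hazard profile for one group
#'
#' @param group group label, one of `"I".."IV"`.
#' @param hazards named list with numeric vectors `DM`, `LR`, `RR`, `death`,
#'   each of length 60, entries in `[0, 1)`: the per-month event probability
#'   conditional on being event-free at the start of the month.
#' @param censor numeric vector of length 60 of monthly censoring hazards in
#'   `[0, 1)`.
#' @return an object of class `group_hazard_profile`.
#' @export
hazard_profile <- function(group, hazards, censor = rep(0, 60)) {
  group <- match.arg(group, group_levels())
  stopifnot(is.list(hazards), all(event_processes() %in% names(hazards)))
  hazards <- hazards[event_processes()]
  for (e in names(hazards)) {
    h <- hazards[[e]]
    if (!is.numeric(h) || length(h) != 60 || any(!is.finite(h)) ||
        any(h < 0) || any(h >= 1)) {
      stop("hazard vector for ", e, " must be length 60 with values in [0, 1)")
    }
  }
  if (!is.numeric(censor) || length(censor) != 60 || any(censor < 0) || any(censor >= 1)) {
    stop("censor hazard must be length 60 with values in [0, 1)")
  }
  structure(list(group = group, hazards = hazards, censor = censor,
                 horizon = 60L),
            class = "group_hazard_profile")
}

#' @export
print.group_hazard_profile <- function(x, ...) {
  df60 <- df_cumulative_incidence(x)[61]
  cat("<group_hazard_profile> group", x$group, "\n")
  cat("  60-month composite disease-failure probability:",
      sprintf("%.3f", df60), "\n")
  for (e in event_processes()) {
    h <- x$hazards[[e]]
    cat(sprintf("  %-5s peak hazard %.4f at month %d\n", e, max(h), which.max(h)))
  }
  invisible(x)
}

#' Composite disease-failure cumulative incidence implied by a profile
#'
#' Closed form under independent monthly event processes:
#' `F_DF[m] = 1 - prod_{j<=m} (1-h_DM[j])(1-h_LR[j])(1-h_RR[j])(1-h_death[j])`.
#'
#' @param profile a [hazard_profile()].
#' @return numeric vector of length 61, cumulative incidence at months 0..60.
#' @export
df_cumulative_incidence <- function(profile) {
  stopifnot(inherits(profile, "group_hazard_profile"))
  surv_m <- Reduce(`*`, lapply(profile$hazards, function(h) 1 - h))
  c(0, 1 - cumprod(surv_m))
}

#' Default calibrated hazard profiles
#'
#' Builds the package's default `group_hazard_profile` for each risk group
#' from a versioned YAML configuration. Each endpoint hazard is a log-normal
#' shaped bump whose density median equals the observed median event time
#' (DM 18.7, LR 27.9, RR 25.0 months) and whose mode sits in the observed
#' peak window (DM month 12, LR/RR month 19); endpoint weights follow the
#' crude event mix (DM : LR : RR = 13.3 : 6.7 : 5.6). A per-group scale is
#' solved numerically so that the composite 60-month disease-failure
#' probability equals the group's five-year target (5.4, 18.6, 34.3, 41.4%
#' for groups I-IV) exactly in the hazard model.
#'
#' @param config path to a profile YAML file; default the file shipped with
#'   the package.
#' @param censoring logical; if `FALSE` the monthly censoring hazard is set
#'   to zero (administrative censoring at month 60 still applies).
#' @return named list of four `group_hazard_profile` objects (`I`..`IV`).
#' @export
default_profiles <- function(config = NULL, censoring = TRUE) {
  if (is.null(config)) {
    config <- system.file("extdata", "default_profiles.yaml", package = "riskvisit",
                          mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(config)
  months <- seq_len(cfg$horizon_months)
  stopifnot(cfg$horizon_months == 60)
  hd <- cfg$death_hazard_monthly
  base <- sapply(names(cfg$endpoints), function(e) {
    ep <- cfg$endpoints[[e]]
    sdlog <- sqrt(log(ep$median / ep$mode))
    ep$weight * stats::dlnorm(months, meanlog = log(ep$median), sdlog = sdlog)
  })
  censor_h <- if (censoring) rep(cfg$censor_hazard_monthly, 60) else rep(0, 60)
  k_max <- 0.999 / max(base)   # keeps every monthly hazard below 1
  profiles <- lapply(group_levels(), function(g) {
    target <- cfg$df_target_5yr[[g]]
    fk <- function(k) {
      hs <- k * base
      (1 - prod((1 - hs[, "DM"]) * (1 - hs[, "LR"]) * (1 - hs[, "RR"]) * (1 - hd))) - target
    }
    k <- stats::uniroot(fk, c(0, k_max), tol = 1e-12)$root
    hs <- k * base
    hazard_profile(g,
                   hazards = list(DM = hs[, "DM"], LR = hs[, "LR"], RR = hs[, "RR"],
                                  death = rep(hd, 60)),
                   censor = censor_h)
  })
  names(profiles) <- group_levels()
  profiles
}
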