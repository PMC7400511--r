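#' Simulate a synthetic survivor cohort
#'
#' Draws a cohort of post-treatment patients whose grouping, covariates and
#' event-time structure emulate a newly diagnosed nasopharyngeal carcinoma
#' population. Time is discrete: months 1..60 from the end of radiotherapy.
#' For every patient, each event process (DM, LR, RR, background death) fires
#' in the first month `m` whose hazard `h[m]` exceeds an independent draw;
#' disease failure (DF) is the earliest of the four. Endpoint-specific records
#' treat competing failures as censoring at their occurrence. Covariates
#' (T, N, EBV DNA) are drawn so that the clinic-molecular grouping holds by
#' construction; the remaining covariates follow the training-cohort marginal
#' frequencies and are independent of event times unless `hazard_ratios`
#' is supplied.
#'
#' @param profiles named list of [hazard_profile()] objects keyed by group;
#'   default [default_profiles()].
#' @param n_per_group named integer vector of patients per group (names
#'   `"I".."IV"`; missing groups mean zero patients).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param hazard_ratios optional named numeric vector of proportional effects
#'   on all recurrence hazards for patients with the named boolean trait
#'   (e.g. `c(smoking = 1.3)`); used to exercise risk adjustment.
#' @return a `data.frame` of class `npc_cohort`, one row per patient, with the
#'   documented cohort columns (see [write_cohort()]).
#' @examples
#' coh <- simulate_cohort(n_per_group = c(I = 5, IV = 5), seed = 1)
#' table(coh$group)
#' @export
simulate_cohort <- function(profiles = default_profiles(),
                            n_per_group = c(I = 100, II = 100, III = 100, IV = 100),
                            seed = 1L,
                            hazard_ratios = NULL) {
  stopifnot(is.numeric(n_per_group), all(n_per_group >= 0))
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% group_levels())) {
    stop("n_per_group must be named with group labels I-IV")
  }
  for (g in names(n_per_group)) {
    if (n_per_group[[g]] > 0 && is.null(profiles[[g]])) {
      stop("no hazard profile supplied for group ", g)
    }
  }
  set.seed(as.integer(seed))
  pieces <- lapply(names(n_per_group), function(g) {
    n <- as.integer(n_per_group[[g]])
    if (n == 0) return(NULL)
    simulate_group(profiles[[g]], g, n, hazard_ratios)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0) {
    coh <- empty_cohort()
  } else {
    coh <- do.call(rbind, pieces)
    coh$patient_id <- sprintf("P%05d", seq_len(nrow(coh)))
    rownames(coh) <- NULL
  }
  class(coh) <- c("npc_cohort", "data.frame")
  coh
}

# One group's patients: covariates consistent with the group, then event times.
simulate_group <- function(profile, group, n, hazard_ratios) {
  cov <- draw_covariates(group, n)
  stopifnot(all(assign_group(cov$t_category, cov$n_category, cov$ebv_dna) == group))

  hr <- rep(1, n)
  if (!is.null(hazard_ratios)) {
    for (v in names(hazard_ratios)) {
      if (!v %in% names(cov)) stop("hazard_ratios refers to unknown covariate ", v)
      hr <- hr * ifelse(as.logical(cov[[v]]), hazard_ratios[[v]], 1)
    }
  }

  # First-passage month for each process: inverse-CDF draw on the discrete
  # survival curve; Inf when no event by month 60.
  draw_first <- function(h, scale = rep(1, n)) {
    # h: length-60 hazard; scale: per-patient multiplier
    hm <- outer(scale, h)                      # n x 60
    hm[hm > 0.999] <- 0.999
    surv <- t(apply(1 - hm, 1, cumprod))       # S(m)
    u <- stats::runif(n)
    # event at first m with 1 - S(m) >= u
    idx <- max.col(cbind(1 - surv >= u, TRUE), ties.method = "first")
    ifelse(idx > 60, Inf, idx)
  }

  t_dm <- draw_first(profile$hazards$DM, hr)
  t_lr <- draw_first(profile$hazards$LR, hr)
  t_rr <- draw_first(profile$hazards$RR, hr)
  t_death <- draw_first(profile$hazards$death)
  t_cens <- draw_first(profile$censor)
  censor_time <- pmin(t_cens, profile$horizon)

  t_all <- cbind(DM = t_dm, LR = t_lr, RR = t_rr, death = t_death)
  t_df <- apply(t_all, 1, min)
  df_event <- is.finite(t_df) & t_df <= censor_time
  df_time <- ifelse(df_event, t_df, NA_real_)

  # Competing failures censor the other endpoints at their occurrence.
  comp_event <- function(tt) {
    others <- pmin(t_df, censor_time)  # first of any failure/death/censoring
    ev <- is.finite(tt) & tt <= others
    list(time = ifelse(ev, tt, NA_real_), event = ev)
  }
  dm <- comp_event(t_dm); lr <- comp_event(t_lr); rr <- comp_event(t_rr)

  out <- data.frame(patient_id = rep(NA_character_, n), cov,
                    df_time = df_time, df_event = df_event,
                    dm_time = dm$time, dm_event = dm$event,
                    lr_time = lr$time, lr_event = lr$event,
                    rr_time = rr$time, rr_event = rr$event,
                    censor_time = as.numeric(censor_time),
                    stringsAsFactors = FALSE)
  out[cohort_columns()]
}

# Covariates: T/N/EBV jointly consistent with the group; the rest from the
# training-cohort marginal frequencies (age < 45: 48.6%; male 74.1%;
# smoking 36.0%; alcohol 14.1%; family history 26.7%; HGB <= 130 g/L: 18.4%;
# ALB <= 40 g/L: 9.5%; CRP <= 3 mg/L: 69.7%; LDH <= 245 IU/L: 91.8%;
# EBV DNA > 2000 copies/mL: 53.7%).
draw_covariates <- function(group, n) {
  # EBV DNA ~ log-normal calibrated so P(> 2000) ~ 0.537 unconditionally;
  # truncated where group membership constrains it.
  ebv_meanlog <- log(2000) + 0.0928 * 2.5
  ebv_sdlog <- 2.5
  r_ebv <- function(n, upper = Inf, lower = 0) {
    plo <- stats::plnorm(lower, ebv_meanlog, ebv_sdlog)
    phi <- stats::plnorm(upper, ebv_meanlog, ebv_sdlog)
    round(stats::qlnorm(plo + stats::runif(n) * (phi - plo), ebv_meanlog, ebv_sdlog), 1)
  }
  t_marg <- c(T1 = 0.104, T2 = 0.178, T3 = 0.475, T4 = 0.243)
  n_marg <- c(N0 = 0.128, N1 = 0.462, N2 = 0.308, N3 = 0.103)
  samp <- function(lev, w, n) sample(lev, n, replace = TRUE, prob = w[lev] / sum(w[lev]))

  if (group == "I") {
    tc <- rep("T1", n); nc <- rep("N0", n); ebv <- r_ebv(n)
  } else if (group == "II") {
    nc <- samp(c("N0", "N1", "N2"), n_marg, n)
    tc <- ifelse(nc == "N0", samp(c("T2", "T3"), t_marg, n),
                 samp(c("T1", "T2", "T3"), t_marg, n))
    ebv <- ifelse(nc == "N2", r_ebv(n, upper = 2000), r_ebv(n))
  } else if (group == "III") {
    pat <- sample(c("n2hi", "t4"), n, replace = TRUE, prob = c(0.55, 0.45))
    tc <- ifelse(pat == "t4", "T4", samp(c("T1", "T2", "T3"), t_marg, n))
    nc <- ifelse(pat == "t4", samp(c("N0", "N1", "N2"), n_marg, n), "N2")
    # lower bound sits on the 0.1 copies/mL reporting grid so that rounding
    # cannot drop a draw back to the 2000 cut-off (which would flip the group)
    ebv <- ifelse(pat == "n2hi", r_ebv(n, lower = 2000.05), r_ebv(n))
  } else {
    tc <- samp(paste0("T", 1:4), t_marg, n); nc <- rep("N3", n); ebv <- r_ebv(n)
  }

  data.frame(
    age = pmax(18, pmin(85, round(stats::rnorm(n, 45.4, 11)))),
    sex = sample(c("male", "female"), n, TRUE, c(0.741, 0.259)),
    smoking = stats::runif(n) < 0.360,
    alcohol = stats::runif(n) < 0.141,
    family_history = stats::runif(n) < 0.267,
    ebv_dna = ebv,
    hgb = round(stats::rnorm(n, 141, 12.2), 1),
    alb = round(stats::rnorm(n, 44.6, 3.5), 1),
    crp = round(stats::rlnorm(n, 0.48, 1.2), 2),
    ldh = round(stats::rnorm(n, 185, 43), 1),
    t_category = tc,
    n_category = nc,
    group = rep(group, n),
    stringsAsFactors = FALSE
  )
}

cohort_columns <- function() {
  c("patient_id", "age", "sex", "smoking", "alcohol", "family_history",
    "ebv_dna", "hgb", "alb", "crp", "ldh", "t_category", "n_category", "group",
    "df_time", "df_event", "dm_time", "dm_event", "lr_time", "lr_event",
    "rr_time", "rr_event", "censor_time")
}

empty_cohort <- function() {
  cols <- cohort_columns()
  coh <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  chr <- c("patient_id", "sex", "t_category", "n_category", "group")
  num <- c("age", "ebv_dna", "hgb", "alb", "crp", "ldh",
           "df_time", "dm_time", "lr_time", "rr_time", "censor_time")
  for (cc in chr) coh[[cc]] <- character(0)
  for (cc in num) coh[[cc]] <- numeric(0)
  coh
}

#' @export
print.npc_cohort <- function(x, ...) {
  cat("<npc_cohort>", nrow(x), "patients\n")
  if (nrow(x) > 0) {
    tab <- table(factor(x$group, levels = group_levels()))
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    cat("  disease failures:", sum(x$df_event), sprintf("(%.1f%%)", 100 * mean(x$df_event)), "\n")
  }
  invisible(x)
}

#' Observation time and event status for one endpoint
#'
#' For `DF` the observation time is the failure time when one occurred and
#' the censoring time otherwise. For `DM`/`LR`/`RR`, competing failures
#' (including death) censor the endpoint at their occurrence.
#'
#' @param cohort an `npc_cohort` data frame.
#' @param endpoint one of `"DF"`, `"DM"`, `"LR"`, `"RR"`.
#' @return data frame with columns `time`, `status` (1 event, 0 censored) and
#'   `group`.
#' @export
endpoint_times <- function(cohort, endpoint = c("DF", "DM", "LR", "RR")) {
  endpoint <- match.arg(endpoint)
  key <- tolower(endpoint)
  ev <- cohort[[paste0(key, "_event")]]
  tt <- cohort[[paste0(key, "_time")]]
  if (endpoint == "DF") {
    time <- ifelse(ev, tt, cohort$censor_time)
  } else {
    # first competing failure (df_time covers all failure causes) or censoring
    comp <- ifelse(cohort$df_event, pmin(cohort$df_time, cohort$censor_time),
                   cohort$censor_time)
    time <- ifelse(ev, tt, comp)
  }
  data.frame(time = time, status = as.integer(ev), group = cohort$group,
             stringsAsFactors = FALSE)
}
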