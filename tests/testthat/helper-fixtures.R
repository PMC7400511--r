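# Shared fixtures, built once per test run on first use.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# Profile with a single constant-hazard event process (0.01/month DM),
# no censoring, no background death: 60-month DF incidence 1 - 0.99^60.
const_profile <- function(group = "I", h = 0.01) {
  hazard_profile(group, list(DM = rep(h, 60), LR = rep(0, 60),
                             RR = rep(0, 60), death = rep(0, 60)))
}

zero_profile <- function(group = "I") const_profile(group, h = 0)

fx_const20k <- function() fixture("const20k", {
  simulate_cohort(list(I = const_profile()), c(I = 20000), seed = 101)
})

fx_const5k <- function() fixture("const5k", {
  simulate_cohort(list(I = const_profile()), c(I = 5000), seed = 202)
})

# Out-of-bag RSF curves on the constant-hazard cohort (the slow fixture).
fx_rsf_const <- function() fixture("rsf_const", {
  suppressWarnings(fit_rsf_curves(fx_const5k(), "DF", n_trees = 200, seed = 7))
})

fx_profiles <- function() fixture("profiles", default_profiles())
fx_profiles_nocens <- function() fixture("profiles_nocens", default_profiles(censoring = FALSE))

fx_calib20k <- function(group) fixture(paste0("calib20k_", group), {
  np <- setNames(20000L, group)
  simulate_cohort(fx_profiles_nocens(), np, seed = 303 + match(group, c("I", "II", "III", "IV")))
})

# Closed-form DF risk curve implied by a hazard profile (no estimation noise).
profile_curve <- function(profile) {
  monthly_risk_curve(df_cumulative_incidence(profile), group = profile$group,
                     endpoint = "DF", estimator = "closed-form")
}

# Toy Markov parameters: an "alive vs dead" reduction of the six-state model.
toy_markov_params <- function(death_monthly = 0.5, horizon = 3, discount = 0,
                              u_ned = 1) {
  list(label = "toy",
       utilities = list(NED = u_ned, early_recurrence = 0, advanced_recurrence = 0,
                        salvage_treatment = 0, NED_after_salvage = 0, death = 0),
       costs_monthly = list(NED = 0, early_recurrence = 0, advanced_recurrence = 0,
                            salvage_treatment = 0, NED_after_salvage = 0, death = 0),
       visit_cost = 0,
       transitions = list(ned_death = death_monthly, er_to_salvage = 0.9,
                          er_death = 0.005, ar_to_salvage = 0.7, ar_death = 0.04,
                          salvage_to_ned = 0.12, salvage_death = 0.015,
                          neds_death = 0.003),
       tail_hazard_monthly = 0, early_window_months = 3,
       discount_annual = discount, horizon_cycles = horizon)
}

zero_risk_curve <- function(group = "I") {
  monthly_risk_curve(rep(0, 61), group = group, endpoint = "DF", estimator = "null")
}
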