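km_curve_from <- function(time, status, group = "I") {
  coh <- empty_stub_cohort(length(time))
  coh$df_time <- ifelse(status == 1, time, NA)
  coh$df_event <- status == 1
  coh$censor_time <- ifelse(status == 1, 60, time)
  suppressWarnings(fit_km_curves(coh, "DF"))[[group]]
}

# minimal cohort scaffold with valid group-I covariates
empty_stub_cohort <- function(n) {
  coh <- simulate_cohort(list(I = zero_profile()), c(I = n), seed = 1)
  coh
}

test_that("product-limit curve matches hand computation on tiny inputs", {
  # one patient, event at month 10: F jumps 0 -> 1 at month 10
  cv <- km_curve_from(10, 1)
  expect_equal(cv$F[1:10], rep(0, 10))
  expect_equal(cv$F[11:61], rep(1, 51))

  # 4 patients: events at 5, 5, 10; censored at 8
  # S(5) = 1 - 2/4 = 0.5; S(10) = 0.5 * (1 - 1/1) = 0
  cv <- km_curve_from(c(5, 5, 10, 8), c(1, 1, 1, 0))
  expect_equal(cv$F[6], 0.5)   # month 5
  expect_equal(cv$F[9], 0.5)   # month 8, unchanged
  expect_equal(cv$F[11], 1)    # month 10
})

test_that("KM recovers the constant-hazard cumulative incidence", {
  cv <- suppressWarnings(fit_km_curves(fx_const5k(), "DF"))[["I"]]
  F_true <- 1 - 0.99^60
  se <- sqrt(F_true * (1 - F_true) / 5000)
  expect_lt(abs(cv$F[61] - F_true), 3 * se)
  # curve invariants
  expect_equal(cv$F[1], 0)
  expect_true(all(diff(cv$F) >= 0))
  expect_equal(sum(cv$p), cv$F[61])
})

test_that("an all-censored cohort yields an identically zero RSF curve", {
  coh <- simulate_cohort(list(I = zero_profile()), c(I = 80), seed = 3)
  cvs <- suppressWarnings(fit_rsf_curves(coh, "DF", n_trees = 30, seed = 1))
  expect_equal(cvs[["I"]]$F, rep(0, 61))
})

test_that("groups without patients are omitted with a warning", {
  coh <- simulate_cohort(fx_profiles(), c(I = 40), seed = 2)
  expect_warning(cvs <- fit_km_curves(coh, "DF"), "no patients in group")
  expect_named(cvs, "I")
})

test_that("the RSF fit is deterministic under a fixed seed", {
  coh <- simulate_cohort(fx_profiles(), c(III = 150), seed = 6)
  a <- suppressWarnings(fit_rsf_curves(coh, "DF", n_trees = 40, seed = 99))
  b <- suppressWarnings(fit_rsf_curves(coh, "DF", n_trees = 40, seed = 99))
  expect_identical(a, b)
})

test_that("OOB ensemble recovery of a constant hazard and agreement with KM", {
  # non-informative covariates: the forest should neither help nor hurt
  cv_rsf <- fx_rsf_const()[["I"]]
  cv_km <- suppressWarnings(fit_km_curves(fx_const5k(), "DF"))[["I"]]
  expect_lt(abs(cv_rsf$F[61] - (1 - exp(-0.6))), 0.03)
  expect_lt(mean(abs(cv_rsf$F - cv_km$F)), 0.02)
})

test_that("estimated group risk increases with the underlying hazard", {
  # paired simulations from the calibrated profiles: group order must be
  # recovered by both estimators
  coh <- simulate_cohort(fx_profiles(), c(I = 400, II = 400, III = 400, IV = 400),
                         seed = 8)
  km <- fit_km_curves(coh, "DF")
  f60 <- vapply(km, function(cv) cv$F[61], numeric(1))[group_levels()]
  expect_true(all(diff(f60) > 0))
  rsf <- fit_rsf_curves(coh, "DF", n_trees = 200, seed = 8)
  f60r <- vapply(rsf, function(cv) cv$F[61], numeric(1))[group_levels()]
  expect_true(all(diff(f60r) > 0))
})

test_that("monthly probabilities are conserved first differences, smoothed or not", {
  cv <- suppressWarnings(fit_km_curves(fx_const5k(), "DF"))[["I"]]
  # window 1 is the identity on first differences
  expect_equal(monthly_probability(cv, 1), diff(cv$F))
  # conservation under smoothing
  for (w in c(3, 5, 7)) {
    expect_equal(sum(monthly_probability(cv, w)), cv$F[61])
  }
  expect_error(monthly_probability(cv, 4), "odd")

  # linear F -> constant p
  lin <- monthly_risk_curve(seq(0, 0.6, length.out = 61), "I")
  expect_equal(monthly_probability(lin, 5), rep(0.01, 60))

  # single step of 0.3 at month 15, window 3 -> 0.1 spread over months 14-16
  Fv <- c(rep(0, 15), rep(0.3, 46))
  step <- monthly_risk_curve(Fv, "I")
  p3 <- monthly_probability(step, 3)
  expect_equal(p3[14:16], rep(0.1, 3))
  expect_equal(sum(p3), 0.3)
})

test_that("curve sets survive a CSV round trip", {
  coh <- simulate_cohort(fx_profiles(), c(II = 120, IV = 120), seed = 4)
  cvs <- suppressWarnings(fit_km_curves(coh, "DF"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves(cvs, path)
  back <- read_curves(path)
  expect_named(back, names(cvs))
  for (g in names(cvs)) expect_equal(back[[g]]$F, cvs[[g]]$F, tolerance = 1e-12)
})
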