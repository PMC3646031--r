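# Exact stochastic simulator: distributional oracles, determinism,
# censoring, KM estimation and the conditioned ensemble.

test_that("inert patients never relapse and clearance is tracked", {
  out <- simulate_patient(model1_params(4, 0, 0, 0, 0.5), tau = 3, seed = 5)
  expect_identical(out$relapse_time, Inf)
  expect_false(out$cleared)   # micrometastases persist, they do not clear
  out0 <- simulate_patient(zeroth_params(1e-9, 0.5), tau = 3, seed = 5)
  expect_true(out0$cleared)   # with N = 0 the patient starts cleared
  expect_identical(out0$relapse_time, Inf)
})

test_that("fixed-count Zeroth relapse times are exponential", {
  p <- zeroth_params(1, kappa = 0.23)
  tab <- simulate_cohort(1e4, p, tau = 2, seed = 17,
                         count_dist = list(type = "fixed", n = 1))
  expect_true(all(tab$event == "relapse"))
  ks <- stats::ks.test(tab$time_years - 2, "pexp", rate = 0.23)
  expect_gt(ks$p.value, 0.01)
})

test_that("Model 1 clearance frequency matches competing exponentials", {
  # with mu = 0 each micrometastasis independently disappears with
  # probability lam/(lam+kappa), so P(cleared) = exp(-N_bar kappa/(lam+kappa))
  lam <- 0.3; kap <- 0.15; N_bar <- 1
  p_clear <- exp(-N_bar * kap / (lam + kap))
  set.seed(23)
  p <- model1_params(N_bar, kap, lam, mu = 0, p_M = 0.5)
  cleared <- vapply(1:4000, function(i) simulate_patient(p, 3)$cleared,
                    logical(1))
  se <- sqrt(p_clear * (1 - p_clear) / 4000)
  expect_lt(abs(mean(cleared) - p_clear), 3 * se)
})

test_that("cohort KM curves match the closed-form survival", {
  p <- zeroth_params(1, 0.1)
  tau <- 3
  tab <- simulate_cohort(2e4, p, tau, seed = 31)
  km <- km_estimate(tab)
  for (t in c(2, 5, 9, 14)) {
    i <- max(which(km$time_years <= t + tau))
    th <- escape_survival(p, km$time_years[i] - tau)
    expect_lt(abs(km$rfi[i] - th), 3 * km$se[i])
  }
})

test_that("identical seeds reproduce cohorts exactly", {
  p <- model2_params(1.5, 0.4, 0.3, 0.25)
  a <- simulate_cohort(500, p, tau = 1.5, seed = 99)
  b <- simulate_cohort(500, p, tau = 1.5, seed = 99)
  expect_identical(a, b)
})

test_that("censoring specs behave and are validated", {
  p <- zeroth_params(0, 0)   # no relapses
  tab <- simulate_cohort(100, p, tau = 3,
                         censoring = list(type = "administrative",
                                          T_end = 15), seed = 1)
  expect_true(all(tab$event == "censored"))
  expect_true(all(tab$time_years == 15))
  tab2 <- simulate_cohort(100, zeroth_params(1, 0.1), tau = 3,
                          censoring = list(type = "uniform_entry",
                                           T_accrual = 5, T_end = 15),
                          seed = 2)
  expect_true(all(tab2$time_years <= 15))
  expect_error(simulate_cohort(10, p, 3, censoring = list(type = "bogus")),
               "censoring spec")
  expect_error(simulate_cohort(10, p, 3,
                               censoring = list(type = "administrative")),
               "T_end")
})

test_that("km_estimate reproduces the hand product-limit computation", {
  tab <- structure(data.frame(patient_id = 1:2, time_years = c(1, 2),
                              event = c("relapse", "relapse")),
                   class = c("event_table", "data.frame"))
  km <- km_estimate(tab)
  expect_equal(km$rfi, c(0.5, 0))
  # all censored: survival stays 1
  tab$event <- c("censored", "censored")
  expect_equal(km_estimate(tab)$rfi, 1)
  # censoring after the last event leaves the estimate unchanged
  tab3 <- structure(data.frame(patient_id = 1:3, time_years = c(1, 2, 8),
                               event = c("relapse", "relapse", "censored")),
                    class = c("event_table", "data.frame"))
  expect_equal(km_estimate(tab3)$rfi, c(2/3, 1/3))
  expect_error(km_estimate(data.frame()), "non-empty")
})

test_that("event tables round-trip through CSV", {
  p <- zeroth_params(1, 0.2)
  tab <- simulate_cohort(50, p, tau = 3, seed = 4,
                         censoring = list(type = "administrative",
                                          T_end = 12))
  path <- tempfile(fileext = ".csv")
  write_event_csv(tab, path)
  back <- read_event_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("conditioned ensemble matches conditioned Poisson thinning", {
  p <- zeroth_params(2, 0.1)
  ens <- conditioned_ensemble(p, 5, n_reps = 2e4, seed = 8)
  expect_lt(abs(ens$mean - 2 * exp(-0.5)), 3 * ens$se_mean)
  # t = 0: unconditioned Poisson moments
  ens0 <- conditioned_ensemble(p, 0, n_reps = 2e4, seed = 9)
  expect_lt(abs(ens0$mean - 2), 3 * ens0$se_mean)
  # two-step counts: conditioned mean of state-V micrometastases
  p2 <- model2_params(3, 0, kappa_s = 0.2, kappa_V = 0.1)
  ens2 <- conditioned_ensemble(p2, 5, n_reps = 2e4, seed = 10)
  cm2 <- conditional_moments(p2, 5)
  expect_lt(abs(ens2$mean["V"] - cm2$mean[cm2$type == "V"]),
            3 * ens2$se_mean["V"])
})

test_that("conditioning starvation raises an explicit error", {
  p <- zeroth_params(8, 1.5)   # almost everyone escapes quickly
  expect_error(conditioned_ensemble(p, 10, n_reps = 300, seed = 3),
               "starvation")
})

test_that("escape-rate heterogeneity lowers the late-time hazard", {
  # two cohorts with the same mean kappa: per-patient gamma-distributed
  # rates mix slow progressors into the late-time risk set, flattening the
  # hazard there relative to the homogeneous cohort
  n <- 4e4
  hom <- simulate_cohort(n, zeroth_params(2, 0.2), tau = 3, seed = 61)
  het <- simulate_cohort(n, zeroth_params(2, 0.2), tau = 3, seed = 62,
                         kappa_dist = list(type = "gamma", mean = 0.2,
                                           shape = 0.8))
  hz_hom <- km_bin_hazard(hom, a = 11, b = 15)
  hz_het <- km_bin_hazard(het, a = 11, b = 15)
  expect_lt(hz_het$h, hz_hom$h + 3 * sqrt(hz_hom$se^2 + hz_het$se^2))
})

test_that("the permissive-lineage event cap fails loudly when supercritical", {
  set.seed(77)
  expect_error(
    dormancy:::sim_perm_lineage(kappa = 0, lam = 0, mu = 5, cap = 1000L),
    "event cap")
})
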