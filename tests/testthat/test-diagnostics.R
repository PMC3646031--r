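# Hazard decomposition, increase/peak conditions, ratio sweeps, burden.

test_that("the Zeroth decomposition is pure variance", {
  p <- zeroth_params(2, 0.2)
  d <- hazard_derivative_decomposition(p, 4, n_reps = 2e4, seed = 13)
  expect_equal(d$gain_term, 0)
  expect_lt(abs(d$variance_term - 0.2^2 * 2 * exp(-0.8)), 3 * d$se_variance)
  expect_equal(d$dh_dt, -0.2^2 * 2 * exp(-0.8), tolerance = 1e-4)
  expect_lt(abs(d$residual), 3 * d$se)
})

test_that("t = 0 decompositions match the closed-form building blocks", {
  # Model 3: gain b*N, variance a^2*N, dh/dt = N(b - a^2)
  p3 <- model3_params(2, a = 0.15, b = 0.05)
  d3 <- hazard_derivative_decomposition(p3, 0, n_reps = 2e4, seed = 14)
  expect_lt(abs(d3$gain_term - 0.05 * 2), 3 * d3$se_gain)
  expect_lt(abs(d3$variance_term - 0.15^2 * 2), 3 * d3$se_variance)
  expect_equal(d3$dh_dt, 2 * (0.05 - 0.15^2), tolerance = 1e-4)
  # Model 2: dh/dt(0) = kV kS Ns - kV^2 NV
  p2 <- model2_params(2, 1.5, kappa_s = 0.3, kappa_V = 0.2)
  expect_equal(hazard_derivative(p2, 0), 0.2 * 0.3 * 2 - 0.2^2 * 1.5,
               tolerance = 1e-5)
  # Model 1: dh/dt(0) = kappa N (mu p_M - lam - kappa)
  p1 <- model1_params(1.5, kappa = 0.1, lam = 0.05, mu = 0.4, p_M = 0.6)
  expect_equal(hazard_derivative(p1, 0),
               0.1 * 1.5 * (0.4 * 0.6 - 0.05 - 0.1), tolerance = 1e-5)
})

test_that("decomposition identity holds across models and times", {
  set.seed(15)
  for (m in all_models) {
    for (rep in 1:3) {
      p <- rand_params(m)
      t <- runif1(0.5, 4)
      d <- hazard_derivative_decomposition(p, t, n_reps = 1.5e4)
      expect_lt(abs(d$residual), 3 * d$se + 1e-4)
    }
  }
})

test_that("t = 0 hazard-increase conditions match the numeric derivative", {
  expect_false(hazard_increasing_at(model3_params(2, 0.1, 0.0099), 0)$increasing)
  expect_true(hazard_increasing_at(model3_params(2, 0.1, 0.0101), 0)$increasing)
  expect_true(hazard_increasing_at(model2_params(2, 0, 0.3, 0.2), 0)$increasing)
  set.seed(16)
  for (m in c("model1", "model2", "model3")) {
    for (rep in 1:50) {
      p <- rand_params(m)
      dh <- hazard_derivative(p, 0)
      if (abs(dh) < 1e-8) next     # excluded indeterminate band
      expect_identical(hazard_increase_condition(p)$satisfied, dh > 0)
    }
  }
  # the Zeroth model can never have an increasing hazard
  for (rep in 1:20) {
    p <- rand_params("zeroth")
    expect_false(hazard_increase_condition(p)$satisfied)
    expect_lte(hazard_derivative(p, runif1(0, 20)), 0)
  }
})

test_that("relapse-rate peaks exist exactly when the t=0 condition says so", {
  set.seed(17)
  # Zeroth: never an interior peak
  for (rep in 1:20) {
    expect_null(find_relapse_rate_peak(rand_params("zeroth")))
  }
  pk <- find_relapse_rate_peak(model2_params(5, 0, 0.2, 0.2))
  expect_false(is.null(pk))
  expect_gt(pk$peak_time, 0)
  # analytic check: r = 5 k^2 t e^{-kt} exp(-5(1-(1+kt)e^{-kt})) maximised
  # where d log r/dt = 1/t - k - h(t) = 0; verify stationarity numerically
  eps <- 1e-5
  expect_lt(abs(relapse_rate(model2_params(5, 0, 0.2, 0.2), pk$peak_time + eps) -
                relapse_rate(model2_params(5, 0, 0.2, 0.2), pk$peak_time - eps)),
            1e-6)
  expect_null(find_relapse_rate_peak(model3_params(2, 0.1, 0)))
})

test_that("peak conditions carry the right ratio algebra", {
  p2 <- model2_params(1.5, 1, 0.3, 0.25)
  pc <- peak_condition(p2)
  expect_equal(pc$lhs, 0.3 * 1.5)
  expect_equal(pc$rhs, 0.25 * 1 * 2)
  expect_equal(pc$ratio, pc$rhs / pc$lhs)
  # satisfied iff dr/dt(0) > 0 iff dh/dt(0) > h(0)^2
  set.seed(18)
  for (m in c("model1", "model2", "model3")) {
    for (rep in 1:40) {
      p <- rand_params(m)
      dr0 <- hazard_derivative(p, 0) - hazard_rate(p, 0)^2
      if (abs(dr0) < 1e-8) next
      expect_identical(peak_condition(p)$satisfied, dr0 > 0)
    }
  }
})

test_that("ratio sweeps hit their targets and flag peaks as expected", {
  bases <- list(model1 = model1_params(1, 0.2, 0.001, 2, 0.5),
                model2 = model2_params(1.5, 1, 0.3, 0.25),
                model3 = model3_params(1, 0.1, 0.05))
  for (m in names(bases)) {
    sw <- ratio_sweep(bases[[m]])
    expect_named(sw, c("ratio_2.00", "ratio_1.00", "ratio_0.20",
                       "ratio_0.04"))
    for (e in sw) {
      expect_null(e$error)
      expect_lt(abs(e$achieved - e$target) / e$target, 1e-6)
    }
    expect_null(sw[[1]]$peak)                 # ratio 2: no interior peak
    expect_false(is.null(sw[[3]]$peak))       # ratio 1/5: peak
    expect_false(is.null(sw[[4]]$peak))       # ratio 1/25: peak
    # peaks become more prominent (relative to the initial relapse rate)
    # as the swept parameter decreases
    prominence <- function(e) e$peak$peak_rate / max(e$relapse_rate[1], 1e-12)
    expect_gt(prominence(sw[[4]]), prominence(sw[[3]]))
  }
  # unreachable targets are reported per ratio, not thrown
  stuck <- ratio_sweep(model1_params(1, 0.2, lam = 1.5, mu = 2, p_M = 0.5),
                       target_ratios = c(0.04))
  expect_match(stuck[[1]]$error, "unreachable")
  expect_error(ratio_sweep(zeroth_params(1, 0.1)), "Zeroth")
})

test_that("burden formulas are exact on closed-form hazards", {
  b <- burden_from_hazard(h = 0.02, h_prime = 0, kappa = 0.02)
  expect_equal(b$mean_n, 1)
  expect_equal(b$var_n, 0)
  expect_equal(burden_from_hazard(0, 0, 0.1)$mean_n, 0)
  # Zeroth closed form with analytic h': mean = N e^{-kt}, var likewise
  p <- zeroth_params(2, 0.1)
  tt <- seq(0, 18, by = 0.5)
  h <- hazard_rate(p, tt)
  hp <- -0.1^2 * 2 * exp(-0.1 * tt)
  est <- burden_from_hazard(h, hp, kappa = 0.1)
  truth <- 2 * exp(-0.1 * tt)
  expect_lt(max(abs(est$mean_n - truth) / truth), 1e-6)
  expect_lt(max(abs(est$var_n - truth) / truth), 1e-6)
  expect_warning(burden_from_hazard(0.1, 0.01, 0.1), "floored")
})

test_that("burden estimation from hazard curves enforces applicability", {
  p <- zeroth_params(2, 0.1)
  tt <- seq(3, 23, by = 0.25)
  hc <- hazard_from_km(rfi_curve(p, tt, tau = 3))
  est <- burden_estimates(hc, kappa = 0.1, times = c(8, 13, 18))
  truth <- 2 * exp(-0.1 * (c(8, 13, 18) - 3))
  expect_lt(max(abs(est$mean_n - truth) / truth), 0.01)
  expect_lt(max(abs(est$var_n - truth) / truth), 0.05)
  expect_error(burden_estimates(hc, kappa = 0.1, times = c(8, 30)),
               "beyond the hazard curve")
  # an increasing hazard voids the approximation
  rising <- dormancy:::new_hazard_curve(1:10, seq(0.01, 0.1, by = 0.01),
                                        tau = 1)
  expect_error(burden_estimates(rising, 0.1, times = c(5, 8)), "increasing")
  expect_error(burden_estimates(hc, kappa = 0, times = 8), "positive")
})
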