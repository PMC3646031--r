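# Closed-form survival, hazard, relapse rate and conditioned moments.

test_that("escape survival matches hand-derived values and boundaries", {
  expect_equal(escape_survival(zeroth_params(0, 0.3), 5), 1)
  expect_equal(escape_survival(zeroth_params(1, 0.1), 10),
               exp(-(1 - exp(-1))))
  expect_equal(escape_survival(model2_params(2, 0, 0.2, 0.2), 0), 1)
  # two-stage survival is the hypoexponential no-event probability
  ks <- 0.3; kv <- 0.12; t <- 7
  q_hand <- exp(-ks * t) + ks * (exp(-kv * t) - exp(-ks * t)) / (ks - kv)
  expect_equal(escape_survival(model2_params(1, 0, ks, kv), t),
               exp(-(1 - q_hand)), tolerance = 1e-12)
})

test_that("survival starts at 1, is non-increasing and bounded in [0,1]", {
  set.seed(21)
  tt <- seq(0, 40, length.out = 120)
  for (m in all_models) {
    for (rep in 1:25) {
      p <- rand_params(m)
      s <- escape_survival(p, tt)
      expect_equal(s[1], 1)
      expect_true(all(s >= 0 & s <= 1))
      expect_true(all(diff(s) <= 1e-12))
    }
  }
})

test_that("reduction limits collapse Models 1-3 onto the Zeroth model", {
  tt <- seq(0, 25, length.out = 100)
  z <- escape_survival(zeroth_params(1.7, 0.13), tt)
  m1 <- escape_survival(model1_params(1.7, 0.13, lam = 0, mu = 0, p_M = 0.6),
                        tt)
  m2 <- escape_survival(model2_params(N_s_bar = 0, N_V_bar = 1.7,
                                      kappa_s = 0.4, kappa_V = 0.13), tt)
  m3 <- escape_survival(model3_params(1.7, a = 0.13, b = 0), tt)
  expect_lt(max(abs(m1 - z)), 1e-10)
  expect_lt(max(abs(m2 - z)), 1e-10)
  expect_lt(max(abs(m3 - z)), 1e-10)
})

test_that("two-stage survival is continuous at equal transition rates", {
  t <- seq(0.5, 30, length.out = 40)
  k <- 0.2
  general <- dormancy:::q_two_stage(t, k + 1e-6, k)   # general branch
  limit <- exp(-(k + 5e-7) * t) * (1 + (k + 5e-7) * t)
  expect_lt(max(abs(general - limit)), 1e-8)
})

test_that("degenerate all-zero parameters give survival 1 and hazard 0", {
  for (p in list(zeroth_params(0, 0), model1_params(0, 0, 0, 0, 0),
                 model2_params(0, 0, 0, 0), model3_params(0, 0, 0))) {
    expect_equal(escape_survival(p, c(0, 5, 50)), rep(1, 3))
    expect_equal(hazard_rate(p, c(0, 5, 50)), rep(0, 3))
  }
})

test_that("analytic hazards agree with the log-survival derivative", {
  set.seed(31)
  eps <- 1e-6
  for (m in all_models) {
    for (rep in 1:8) {
      p <- rand_params(m)
      for (t in c(0.5, 3, 12)) {
        num <- -(log(escape_survival(p, t + eps)) -
                 log(escape_survival(p, t - eps))) / (2 * eps)
        expect_equal(hazard_rate(p, t), num, tolerance = 1e-5)
      }
    }
  }
  # Zeroth closed form and its t = 0 value
  p <- zeroth_params(1, 0.1)
  expect_equal(hazard_rate(p, 0), 0.1)
  tt <- seq(0, 20, by = 0.5)
  expect_equal(hazard_rate(p, tt), 0.1 * exp(-0.1 * tt), tolerance = 1e-12)
  # no one-step micrometastases: zero hazard at t = 0+
  expect_equal(hazard_rate(model2_params(3, 0, 0.2, 0.1), 0), 0)
})

test_that("relapse rate integrates to the total relapse probability", {
  p <- zeroth_params(1.3, 0.12)
  total <- stats::integrate(function(t) relapse_rate(p, t), 0, Inf,
                            rel.tol = 1e-10)$value
  expect_equal(total, 1 - exp(-1.3), tolerance = 1e-8)
  # strictly decreasing for the Zeroth model; identically zero without
  # micrometastases
  tt <- seq(0, 30, length.out = 300)
  expect_true(all(diff(relapse_rate(p, tt)) < 0))
  expect_equal(relapse_rate(zeroth_params(0, 0.3), tt), rep(0, 300))
})

test_that("rfi_curve converts between post-resection time and escape clock", {
  p <- zeroth_params(1, 0.1)
  cv <- rfi_curve(p, times = 3, tau = 3)
  expect_equal(cv$rfi, 1)
  cv <- rfi_curve(p, times = c(3, 13), tau = 3)
  expect_equal(cv$rfi[2], exp(-(1 - exp(-1))))
  expect_true(attr(cv, "normalized"))
  z <- rfi_curve(zeroth_params(2, 0.07), seq(3, 15), tau = 3)
  m3 <- rfi_curve(model3_params(2, a = 0.07, b = 0), seq(3, 15), tau = 3)
  expect_equal(m3$rfi, z$rfi, tolerance = 1e-12)
})

test_that("conditioned moments are Poisson where thinning applies", {
  p <- zeroth_params(2.4, 0.15)
  cm <- conditional_moments(p, 5)
  expect_equal(cm$mean, 2.4 * exp(-0.75))
  expect_equal(cm$var, cm$mean)
  # t = 0 recovers the initial Poisson means for every model
  set.seed(41)
  for (m in all_models) {
    p <- rand_params(m)
    cm0 <- conditional_moments(p, 0)
    P <- unclass(p)
    expected <- switch(m,
      zeroth = P$N_bar, model3 = P$N_bar,
      model2 = c(P$N_s_bar, P$N_V_bar),
      model1 = c(P$N_bar * (1 - P$p_M), P$N_bar * P$p_M))
    expect_equal(cm0$mean, expected, tolerance = 1e-10)
    expect_equal(cm0$var[cm0$type != "permissive"],
                 expected[cm0$type != "permissive"], tolerance = 1e-10)
  }
})

test_that("the hazard equals the escape intensity applied to the means", {
  set.seed(51)
  for (m in all_models) {
    for (rep in 1:6) {
      p <- rand_params(m)
      P <- unclass(p)
      for (t in c(0.5, 4, 10)) {
        cm <- conditional_moments(p, t)
        h_from_moments <- switch(m,
          zeroth = P$kappa * attr(cm, "total_mean"),
          model1 = P$kappa * attr(cm, "total_mean"),
          model2 = P$kappa_V * cm$mean[cm$type == "V"],
          model3 = (P$a + P$b * t) * attr(cm, "total_mean"))
        expect_equal(hazard_rate(p, t), h_from_moments, tolerance = 1e-7)
      }
    }
  }
})

test_that("Model 1 conditioned moments match the conditioned ensemble", {
  p <- model1_params(1.5, kappa = 0.12, lam = 0.08, mu = 0.25, p_M = 0.4)
  cm <- conditional_moments(p, 5)
  ens <- conditioned_ensemble(p, 5, n_reps = 3e4, seed = 7)
  for (ty in c("non_permissive", "permissive")) {
    expect_lt(abs(ens$mean[ty] - cm$mean[cm$type == ty]),
              3 * ens$se_mean[ty])
    # variance SE of roughly var * sqrt(2/m) for near-Poisson counts
    se_var <- ens$var[ty] * sqrt(2 / (ens$n_surviving - 1)) +
      stats::sd((ens$counts[, ty] - ens$mean[ty])^2) / sqrt(ens$n_surviving)
    expect_lt(abs(ens$var[ty] - cm$var[cm$type == ty]), 3 * se_var)
  }
})

test_that("Zeroth hazard is non-increasing for any initial count law", {
  tt <- seq(0, 30, length.out = 200)
  for (cd in list(list(type = "poisson", mean = 2.5),
                  list(type = "fixed", n = 3),
                  list(type = "mixture", n = c(0, 1, 6),
                       prob = c(0.3, 0.4, 0.3)))) {
    h <- zeroth_hazard_general(tt, kappa = 0.2, count_dist = cd)
    expect_true(all(diff(h) <= 1e-12))
    s <- zeroth_survival_general(tt, kappa = 0.2, count_dist = cd)
    expect_true(all(diff(s) <= 0) && all(s >= 0 & s <= 1))
  }
})
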