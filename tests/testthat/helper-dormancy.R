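# Shared test helpers: random-but-reasonable parameter draws (rates and
# counts in ranges where a dormancy cohort relapses over decades, and where
# conditioned ensembles keep enough survivors), and a Greenwood-exact
# binned hazard estimator used as an independent oracle for burden tests.

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

# Moderate random parameter draws per model (call under a set seed).
rand_params <- function(model) {
  switch(model,
    zeroth = zeroth_params(N_bar = runif1(0.2, 4), kappa = runif1(0.02, 0.6)),
    model1 = model1_params(N_bar = runif1(0.2, 3), kappa = runif1(0.02, 0.5),
                           lam = runif1(0, 0.4), mu = runif1(0, 0.5),
                           p_M = runif1(0, 1)),
    model2 = model2_params(N_s_bar = runif1(0.2, 3), N_V_bar = runif1(0, 3),
                           kappa_s = runif1(0.02, 0.6),
                           kappa_V = runif1(0.02, 0.6)),
    model3 = model3_params(N_bar = runif1(0.2, 3), a = runif1(0.02, 0.4),
                           b = runif1(0, 0.08)))
}

all_models <- c("zeroth", "model1", "model2", "model3")

# Empirical no-escape (dormancy survival) fraction at escape-clock times,
# from a censoring-free simulated cohort.
empirical_survival <- function(tab, tau, times) {
  esc <- ifelse(tab$event == "relapse", tab$time_years - tau, Inf)
  vapply(times, function(t) mean(esc > t), numeric(1))
}

# Binned hazard with an exact Greenwood-type standard error: the Nelson-
# Aalen increment between a and b divided by the bin width; increments of
# the cumulative-hazard variance are independent, so
# var(h) = (V(b) - V(a)) / (b - a)^2.
km_bin_hazard <- function(tab, a, b) {
  tm <- tab$time_years
  status <- as.integer(tab$event == "relapse")
  finite_max <- max(tm[is.finite(tm)], a, b)
  tm[!is.finite(tm)] <- finite_max + 1
  fit <- survival::survfit(survival::Surv(tm, status) ~ 1)
  cumhaz <- stats::stepfun(fit$time, c(0, fit$cumhaz))
  vhaz <- stats::stepfun(fit$time, c(0, fit$std.err^2))
  w <- b - a
  list(h = (cumhaz(b) - cumhaz(a)) / w,
       se = sqrt(max(vhaz(b) - vhaz(a), 0)) / w)
}
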