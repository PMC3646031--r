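# Hazard-derivative decomposition, hazard-increase and relapse-rate-peak
# conditions, ratio sweeps, and micrometastasis-burden estimation.
#
# The organizing identity: the hazard is the conditioned mean of the total
# escape intensity I (kappa*n, kappa_V*n_V, or kappa(t)*n depending on the
# model), and its derivative splits as
#     dh/dt = E_t[gain of I] - Var_t[I],
# both moments taken among still-dormant patients. Tumourigenicity gains
# push the hazard up; variability in disease course pulls it down, which is
# why increasing hazards are rarely visible in cohort data.

# Per-rep total escape intensity from a conditioned-ensemble count matrix.
escape_intensity_counts <- function(params, counts, t) {
  P <- plist(params)
  switch(model_id(params),
    zeroth = P$kappa * counts[, "micrometastasis"],
    model3 = (P$a + P$b * t) * counts[, "micrometastasis"],
    model2 = P$kappa_V * counts[, "V"],
    model1 = P$kappa * (counts[, "non_permissive"] + counts[, "permissive"]))
}

# Per-rep expected rate of increase of the escape intensity (generator
# applied to I, plus the explicit time derivative for Model 3).
escape_intensity_gain <- function(params, counts, t) {
  P <- plist(params)
  switch(model_id(params),
    zeroth = rep(0, nrow(counts)),
    model3 = P$b * counts[, "micrometastasis"],
    model2 = P$kappa_V * P$kappa_s * counts[, "s"],
    model1 = P$kappa * (P$mu * counts[, "permissive"] -
               P$lam * (counts[, "non_permissive"] + counts[, "permissive"])))
}

#' Decompose the hazard derivative into gain and variance terms
#'
#' Estimates, from a conditioned simulation ensemble, the expected rate of
#' increase of the total escape intensity among dormant patients (the gain
#' term) and the variance of that intensity (the variance term), and
#' computes the hazard derivative independently from the closed-form
#' hazard. The identity `dh/dt = gain - variance` then holds within Monte
#' Carlo error.
#'
#' @param params A `model_params` object.
#' @param t Escape-clock time, years.
#' @param n_reps Ensemble size (patients simulated before conditioning).
#' @param seed Optional integer seed.
#' @return A list of class `decomposition_result`: `t`, `gain_term`,
#'   `variance_term`, `dh_dt` (1/year^2 each), standard errors `se_gain`,
#'   `se_variance`, the combined `se`, `residual = dh_dt -
#'   (gain - variance)`, and `n_surviving`.
#' @export
hazard_derivative_decomposition <- function(params, t, n_reps = 2e4,
                                            seed = NULL) {
  ens <- conditioned_ensemble(params, t, n_reps, seed = seed)
  I <- escape_intensity_counts(params, ens$counts, t)
  g <- escape_intensity_gain(params, ens$counts, t)
  m <- ens$n_surviving
  gain <- mean(g)
  v <- stats::var(I)
  se_gain <- stats::sd(g) / sqrt(m)
  se_var <- stats::sd((I - mean(I))^2) / sqrt(m)
  dh <- hazard_derivative(params, t)
  structure(list(t = t, gain_term = gain, variance_term = v, dh_dt = dh,
                 se_gain = se_gain, se_variance = se_var,
                 se = sqrt(se_gain^2 + se_var^2),
                 residual = dh - (gain - v), n_surviving = m),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("<hazard derivative decomposition at t = ", x$t, " y>\n",
      "  dh/dt    = ", format(x$dh_dt, digits = 5), " 1/y^2\n",
      "  gain     = ", format(x$gain_term, digits = 5), " 1/y^2\n",
      "  variance = ", format(x$variance_term, digits = 5), " 1/y^2\n",
      "  residual = ", format(x$residual, digits = 3),
      " (MC se ", format(x$se, digits = 3), ", n = ", x$n_surviving, ")\n",
      sep = "")
  invisible(x)
}

#' Is the hazard rate increasing at time t?
#'
#' Sign of the hazard derivative (numeric, from the closed-form hazard).
#'
#' @inheritParams hazard_derivative_decomposition
#' @return List with `increasing` (logical) and `margin` (dh/dt, 1/year^2).
#' @export
hazard_increasing_at <- function(params, t) {
  dh <- hazard_derivative(params, t)
  list(increasing = dh > 0, margin = dh)
}

#' Analytic hazard-increase condition at t = 0 (Poisson initial counts)
#'
#' The hazard is increasing at 0+ iff `lhs > rhs`: Model 1
#' `mu p_M > lam + kappa`; Model 2 `kappa_s N_s_bar > kappa_V N_V_bar`;
#' Model 3 `b > a^2`. The Zeroth model's hazard is never increasing.
#'
#' @param params A `model_params` object.
#' @return List with `lhs`, `rhs`, `satisfied`.
#' @export
hazard_increase_condition <- function(params) {
  P <- plist(params)
  cond <- switch(model_id(params),
    zeroth = list(lhs = 0, rhs = P$kappa^2 * P$N_bar),
    model1 = list(lhs = P$mu * P$p_M, rhs = P$lam + P$kappa),
    model2 = list(lhs = P$kappa_s * P$N_s_bar, rhs = P$kappa_V * P$N_V_bar),
    model3 = list(lhs = P$b, rhs = P$a^2))
  cond$satisfied <- model_id(params) != "zeroth" && cond$lhs > cond$rhs
  cond
}

#' Analytic relapse-rate-peak condition at t = 0 (Poisson initial counts)
#'
#' The relapse rate `r = h f` rises from t = 0 iff
#' `dh/dt(0) > h(0)^2`, i.e. `lhs > rhs` with: Model 1 `mu p_M` vs
#' `lam + kappa + kappa N_bar`; Model 2 `kappa_s N_s_bar` vs
#' `kappa_V N_V_bar (1 + N_V_bar)`; Model 3 `b` vs `a^2 (1 + N_bar)`. The
#' Zeroth model can never satisfy it. The numeric peak search
#' ([find_relapse_rate_peak()]) remains the ground truth for peak
#' existence.
#'
#' @param params A `model_params` object.
#' @return List with `lhs`, `rhs`, `ratio` (= rhs/lhs, the quantity swept
#'   in [ratio_sweep()]), `satisfied`.
#' @export
peak_condition <- function(params) {
  P <- plist(params)
  cond <- switch(model_id(params),
    zeroth = list(lhs = 0, rhs = P$kappa^2 * P$N_bar * (1 + P$N_bar)),
    model1 = list(lhs = P$mu * P$p_M,
                  rhs = P$lam + P$kappa + P$kappa * P$N_bar),
    model2 = list(lhs = P$kappa_s * P$N_s_bar,
                  rhs = P$kappa_V * P$N_V_bar * (1 + P$N_V_bar)),
    model3 = list(lhs = P$b, rhs = P$a^2 * (1 + P$N_bar)))
  cond$ratio <- if (cond$lhs > 0) cond$rhs / cond$lhs else Inf
  cond$satisfied <- model_id(params) != "zeroth" && cond$lhs > cond$rhs
  cond
}

#' Locate an interior maximum of the relapse rate
#'
#' Dense grid search over (0, t_max] followed by golden-section refinement
#' ([stats::optimize()]) in the bracketing interval. Returns `NULL` when
#' the maximum sits at the t = 0 boundary (no interior peak).
#'
#' @param params A `model_params` object.
#' @param t_max Search horizon, escape-clock years.
#' @param grid_n Grid resolution.
#' @return `NULL`, or a list with `peak_time` and `peak_rate`.
#' @export
find_relapse_rate_peak <- function(params, t_max = 40, grid_n = 512L) {
  stopifnot(t_max > 0)
  tt <- seq(0, t_max, length.out = grid_n)
  r <- relapse_rate(params, tt)
  if (all(r <= 0)) return(NULL)
  i <- which.max(r)
  if (i == 1L) return(NULL)
  lo <- tt[max(i - 1L, 1L)]
  hi <- tt[min(i + 1L, grid_n)]
  opt <- stats::optimize(function(x) relapse_rate(params, x),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  # reject spurious "peaks" from flat numerical noise at the boundary
  if (opt$objective <= r[1] * (1 + 1e-9)) return(NULL)
  list(peak_time = opt$maximum, peak_rate = opt$objective)
}

sweep_default_param <- function(model) {
  switch(model, model1 = "kappa", model2 = "N_V_bar", model3 = "a",
         stop("ratio sweeps apply to models 1-3 (the Zeroth model has no ",
              "peak condition to tune)", call. = FALSE))
}

#' Sweep a parameter to preset relapse-rate-peak ratios
#'
#' For each target ratio `rhs/lhs` of the peak condition (see
#' [peak_condition()]), root-finds the value of the swept parameter that
#' achieves it, and evaluates the resulting RFI curve, relapse rate and
#' peak flag. The default swept parameters -- `kappa` (Model 1), `N_V_bar`
#' (Model 2), `a` (Model 3) -- are those whose reduction mimics therapies
#' that induce growth restriction, or remove one-step micrometastases,
#' without preventing tumourigenicity increases: peaks appear as the swept
#' parameter decreases (ratios below 1).
#'
#' @param base_params A `model_params` object for Model 1, 2 or 3.
#' @param target_ratios Ratios rhs/lhs to achieve (default `c(2, 1, 1/5,
#'   1/25)`).
#' @param sweep_param Parameter name to tune; default depends on the model.
#' @param t_max Horizon for curves and peak search (escape-clock years).
#' @param grid_n Number of grid points for the returned curves.
#' @param upper Upper bound for the root search on the swept parameter.
#' @return A list of class `ratio_sweep`, one entry per ratio: `target`,
#'   `achieved`, `value` (tuned parameter), `params`, `peak`
#'   ([find_relapse_rate_peak()] result or `NULL`), `times`, `rfi`,
#'   `relapse_rate`; unreachable ratios get an `error` string instead.
#' @export
ratio_sweep <- function(base_params, target_ratios = c(2, 1, 1/5, 1/25),
                        sweep_param = NULL, t_max = 40, grid_n = 201L,
                        upper = 50) {
  stopifnot(inherits(base_params, "model_params"))
  model <- model_id(base_params)
  if (is.null(sweep_param)) sweep_param <- sweep_default_param(model)
  if (!sweep_param %in% names(base_params)) {
    stop("'", sweep_param, "' is not a parameter of ", model, call. = FALSE)
  }
  ratio_at <- function(x) {
    p <- unclass(base_params)
    p[[sweep_param]] <- x
    peak_condition(make_params(model, p))$ratio
  }
  tt <- seq(0, t_max, length.out = grid_n)
  out <- lapply(target_ratios, function(target) {
    root <- tryCatch({
      fn <- function(x) ratio_at(x) - target
      stats::uniroot(fn, lower = 0, upper = upper, tol = 1e-10,
                     extendInt = "no")
    }, error = function(e) e)
    if (inherits(root, "error")) {
      return(list(target = target,
                  error = paste0("ratio ", format(target),
                                 " unreachable for '", sweep_param,
                                 "' in [0, ", upper, "]: ",
                                 conditionMessage(root))))
    }
    p <- unclass(base_params)
    p[[sweep_param]] <- root$root
    params <- make_params(model, p)
    list(target = target, achieved = ratio_at(root$root),
         value = root$root, sweep_param = sweep_param, params = params,
         peak = find_relapse_rate_peak(params, t_max = t_max),
         times = tt, rfi = escape_survival(params, tt),
         relapse_rate = relapse_rate(params, tt))
  })
  names(out) <- paste0("ratio_", format(target_ratios))
  structure(out, class = "ratio_sweep", model = model,
            sweep_param = sweep_param)
}

#' Exact burden formulas from a hazard value and its derivative
#'
#' Once tumourigenicity has stopped changing (late times: all seeding-
#' capable patients have relapsed, two-step micrometastases have taken
#' their first step, the escape rate has stopped rising), every model
#' collapses to the Zeroth model, and the conditioned micrometastasis
#' burden follows from the hazard alone: `mean_n = h / kappa`,
#' `var_n = -h' / kappa^2`.
#'
#' @param h Hazard value(s), 1/year.
#' @param h_prime Hazard derivative(s), 1/year^2.
#' @param kappa Assumed escape rate, 1/year (> 0). `kappa = 1/50` per year
#'   corresponds to escape within 50 years.
#' @return data.frame with `mean_n`, `var_n`, `sd_n`.
#' @export
burden_from_hazard <- function(h, h_prime, kappa) {
  if (kappa <= 0) stop("'kappa' must be positive", call. = FALSE)
  var_n <- -h_prime / kappa^2
  if (any(var_n < 0)) {
    warning("negative var_n (locally increasing hazard) floored at 0")
    var_n <- pmax(var_n, 0)
  }
  data.frame(mean_n = h / kappa, var_n = var_n, sd_n = sqrt(var_n))
}

#' Estimate the hidden micrometastasis burden from a hazard curve
#'
#' Applies the late-time collapse formulas `mean_n = h(t)/kappa`,
#' `var_n = -h'(t)/kappa^2` to a (smoothed, possibly extrapolated) hazard
#' curve, at the requested times post-resection. The collapse approximation
#' applies only from a time beyond which the hazard is non-increasing, so
#' an increasing hazard over the requested window is an error.
#'
#' @param hc A [hazard_curve].
#' @param kappa Assumed escape rate, 1/year (> 0).
#' @param times Years post-resection at which to estimate the burden; must
#'   lie within the curve (extrapolate first if needed).
#' @param increase_tol Tolerated rise between consecutive curve points in
#'   the window before declaring the approximation inapplicable (absolute,
#'   1/year; allows noise-level wiggles in estimated hazards).
#' @return A data.frame of class `burden_estimate` with `time_years`,
#'   `mean_n`, `var_n`, `sd_n`; `kappa` is kept as an attribute.
#' @export
burden_estimates <- function(hc, kappa, times, increase_tol = 0) {
  stopifnot(inherits(hc, "hazard_curve"))
  if (kappa <= 0) stop("'kappa' must be positive", call. = FALSE)
  tm <- hc$time_years
  if (any(times < min(tm) - 1e-9) || any(times > max(tm) + 1e-9)) {
    stop("requested times extend beyond the hazard curve; use ",
         "extrapolate_hazard() first", call. = FALSE)
  }
  win <- tm >= min(times) - 1e-9
  if (any(diff(hc$h[win]) > increase_tol)) {
    stop("hazard is increasing over the requested window; the late-time ",
         "collapse approximation (mean_n = h/kappa) does not apply",
         call. = FALSE)
  }
  hfun <- stats::approxfun(tm, hc$h, rule = 2)
  spacing <- min(diff(tm))
  hp <- (hfun(pmin(times + spacing, max(tm))) -
         hfun(pmax(times - spacing, min(tm)))) /
        (pmin(times + spacing, max(tm)) - pmax(times - spacing, min(tm)))
  out <- burden_from_hazard(hfun(times), hp, kappa)
  out <- cbind(time_years = times, out)
  structure(out, class = c("burden_estimate", "data.frame"), kappa = kappa)
}
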