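# Monte Carlo random-search fitting: parameters are sampled uniformly over
# a bounded box and the best total squared deviation (tsd) between the
# model's closed-form RFI curve and the data wins. Random search (no local
# refinement) is deliberate: with ~15 digitized points and 2-5 parameters
# the objective is cheap, flat near its minimum, and the method's sampling
# noise is itself informative about identifiability.

#' Default uniform sampling bounds for a model's parameters
#'
#' Mean-count parameters range over [0, 50], rates over [0, 2] per year,
#' `p_M` over [0, 1] and the escape-rate slope `b` over [0, 0.5] per
#' year squared.
#'
#' @param model Model id string.
#' @return Named list of length-2 numeric vectors `c(lower, upper)`.
#' @export
default_bounds <- function(model) {
  count <- c(0, 50); rate <- c(0, 2)
  switch(match.arg(model, c("zeroth", "model1", "model2", "model3")),
         zeroth = list(N_bar = count, kappa = rate),
         model1 = list(N_bar = count, kappa = rate, lam = rate, mu = rate,
                       p_M = c(0, 1)),
         model2 = list(N_s_bar = count, N_V_bar = count, kappa_s = rate,
                       kappa_V = rate),
         model3 = list(N_bar = count, a = rate, b = c(0, 0.5)))
}

#' Configuration for a Monte Carlo fit
#'
#' @param model Model id string.
#' @param tau Growth time in years (fixed, not fitted).
#' @param bounds Named list of `c(lower, upper)` per parameter; defaults to
#'   [default_bounds()].
#' @param n_samples Number of uniform draws (default 1e6).
#' @param seed Integer seed; required so fits are reproducible.
#' @param top_k How many runner-up parameter sets to keep.
#' @return A `fit_config` object.
#' @export
fit_config <- function(model, tau, bounds = default_bounds(model),
                       n_samples = 1e6, seed = 1L, top_k = 5L) {
  model <- match.arg(model, c("zeroth", "model1", "model2", "model3"))
  nm <- model_param_names(model)
  if (!setequal(names(bounds), nm)) {
    stop("bounds must be named exactly: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  for (b in bounds) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] > b[2]) {
      stop("each bound must be a finite c(lower, upper) with lower <= upper",
           call. = FALSE)
    }
  }
  if (n_samples < 1) stop("'n_samples' must be >= 1", call. = FALSE)
  structure(list(model = model, tau = check_tau(tau), bounds = bounds[nm],
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 top_k = as.integer(top_k)),
            class = "fit_config")
}

check_fit_curve <- function(curve, tau) {
  stopifnot(inherits(curve, "rfi_curve"))
  if (!isTRUE(attr(curve, "normalized"))) {
    stop("curve must be normalized at tau (see normalize_at_tau())",
         call. = FALSE)
  }
  ctau <- attr(curve, "tau")
  if (!is.null(tau) && abs(ctau - tau) > 1e-9) {
    stop("curve is normalized at tau = ", ctau,
         " but the fit requests tau = ", tau, call. = FALSE)
  }
  if (!any(curve$time_years >= ctau)) {
    stop("no data points at or beyond tau", call. = FALSE)
  }
  curve
}

#' Total squared deviation between a model and a normalized RFI curve
#'
#' The fitting objective: the sum over data points (at times >= tau) of the
#' squared difference between the model's closed-form RFI value and the
#' data value.
#'
#' @param params A `model_params` object.
#' @param curve A normalized [rfi_curve].
#' @return Non-negative scalar tsd.
#' @export
objective <- function(params, curve) {
  stopifnot(inherits(params, "model_params"))
  curve <- check_fit_curve(curve, NULL)
  tau <- attr(curve, "tau")
  f_model <- escape_survival(params, curve$time_years - tau)
  sum((f_model - curve$rfi)^2)
}

#' Fit a model to an RFI curve by Monte Carlo random search
#'
#' Draws `n_samples` parameter points uniformly from the configured box,
#' evaluates the total squared deviation of each against the data, and
#' returns the argmin (plus the `top_k` runners-up). Deterministic given
#' the seed, and the draw stream is nested: a fit with fewer samples uses a
#' prefix of the draws of a fit with more, so the best tsd is non-increasing
#' in `n_samples` at a common seed.
#'
#' @param config A [fit_config].
#' @param curve A normalized [rfi_curve].
#' @param polish Off by default, mirroring the plain random-search method.
#'   When `TRUE`, the best draw is refined by box-constrained local
#'   optimization (`optim(method = "L-BFGS-B")`) within the bounds; the
#'   unpolished search result is kept in `top`.
#' @return A `fit_result`: list with `model`, `params` (best-fit
#'   `model_params`), `tsd`, `n_samples`, `seed`, `bounds`, and `top`
#'   (data.frame of the best `top_k` draws).
#' @export
fit_monte_carlo <- function(config, curve, polish = FALSE) {
  stopifnot(inherits(config, "fit_config"))
  curve <- check_fit_curve(curve, config$tau)
  nm <- names(config$bounds)
  k <- length(nm)
  n <- config$n_samples
  lo <- vapply(config$bounds, `[`, numeric(1), 1L)
  hi <- vapply(config$bounds, `[`, numeric(1), 2L)
  set.seed(config$seed)
  draws <- matrix(stats::runif(k * n), nrow = k)   # columns = samples
  draws <- draws * (hi - lo) + lo
  rownames(draws) <- nm
  t_esc <- curve$time_years - config$tau
  f_data <- curve$rfi
  top_k <- min(config$top_k, n)
  best_tsd <- rep(Inf, top_k)
  best_idx <- integer(top_k)
  chunk <- 50000L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    P <- lapply(seq_len(k), function(i) draws[i, idx])
    names(P) <- nm
    tsd <- numeric(length(idx))
    for (j in seq_along(t_esc)) {
      tsd <- tsd + (esc_surv(config$model, t_esc[j], P) - f_data[j])^2
    }
    cand_t <- c(best_tsd, tsd)
    cand_i <- c(best_idx, idx)
    ord <- order(cand_t)[seq_len(top_k)]
    best_tsd <- cand_t[ord]
    best_idx <- cand_i[ord]
  }
  keep <- is.finite(best_tsd)
  best_tsd <- best_tsd[keep]; best_idx <- best_idx[keep]
  top <- as.data.frame(t(draws[, best_idx, drop = FALSE]))
  top$tsd <- best_tsd
  rownames(top) <- NULL
  best_par <- unlist(top[1, nm])
  best <- best_tsd[1]
  if (polish) {
    obj_vec <- function(x) {
      P <- as.list(x); names(P) <- nm
      sum((esc_surv(config$model, t_esc, P) - f_data)^2)
    }
    opt <- stats::optim(best_par, obj_vec, method = "L-BFGS-B",
                        lower = lo, upper = hi)
    if (opt$value < best) {
      best <- opt$value
      best_par <- opt$par
    }
  }
  structure(list(model = config$model,
                 params = make_params(config$model, as.list(best_par)),
                 tsd = best, n_samples = n, seed = config$seed,
                 tau = config$tau, bounds = config$bounds, top = top,
                 polished = polish),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result: ", x$model, ", tsd = ", format(x$tsd, digits = 6),
      " from ", x$n_samples, " draws (seed ", x$seed, ")>\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Fit all four models to one curve with matched budgets
#'
#' Runs [fit_monte_carlo()] for each requested model with the same number
#' of samples and seed, and ranks the results by total squared deviation.
#'
#' @param curve A normalized [rfi_curve].
#' @param tau Growth time, years.
#' @param models Character vector of model ids (default all four).
#' @param n_samples Samples per model.
#' @param seed Integer seed shared by all fits.
#' @param bounds Optional named list (per model id) of bounds overrides.
#' @return A data.frame ranked by tsd (columns `model`, `tsd`), with the
#'   full `fit_result` objects in attribute `"fits"`.
#' @export
compare_models <- function(curve, tau,
                           models = c("zeroth", "model1", "model2", "model3"),
                           n_samples = 1e5, seed = 1L, bounds = NULL) {
  fits <- lapply(models, function(m) {
    b <- if (!is.null(bounds) && !is.null(bounds[[m]])) bounds[[m]] else
      default_bounds(m)
    fit_monte_carlo(fit_config(m, tau = tau, bounds = b,
                               n_samples = n_samples, seed = seed), curve)
  })
  names(fits) <- models
  ranking <- data.frame(model = models,
                        tsd = vapply(fits, `[[`, numeric(1), "tsd"))
  ranking <- ranking[order(ranking$tsd), ]
  rownames(ranking) <- NULL
  attr(ranking, "fits") <- fits
  ranking
}

#' Read a fit configuration from JSON or YAML
#'
#' The file must provide `model` and `tau`, and may provide `bounds`
#' (mapping parameter name to `[lower, upper]`), `n_samples`, `seed`,
#' `top_k`.
#'
#' @param path File path (`.json`, `.yaml`/`.yml`).
#' @return A [fit_config].
#' @export
read_fit_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw$model) || is.null(raw$tau)) {
    stop("fit config must provide 'model' and 'tau'", call. = FALSE)
  }
  args <- list(model = raw$model, tau = raw$tau)
  if (!is.null(raw$bounds)) {
    args$bounds <- lapply(raw$bounds, as.numeric)
  }
  for (fld in c("n_samples", "seed", "top_k")) {
    if (!is.null(raw[[fld]])) args[[fld]] <- raw[[fld]]
  }
  do.call(fit_config, args)
}

#' Write a fit result as JSON
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(model = fit$model, params = unclass(fit$params),
              tsd = fit$tsd, n_samples = fit$n_samples, seed = fit$seed,
              tau = fit$tau, bounds = fit$bounds, top = fit$top)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
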