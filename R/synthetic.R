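# Study-like synthetic KM fixtures. The real inputs to this kind of analysis
# are RFI curves digitized from published figures of large follow-up studies
# (a 15-year, 6399-patient cohort in two age strata; a 10-year, 1187-patient
# cohort in two ER strata). The generator emulates such curves: closed-form
# model values on a figure-like grid, binomial sampling noise at the cohort
# size, optional digitization jitter, monotone correction, normalization at
# tau.

#' Define a synthetic KM scenario
#'
#' @param name Scenario name (used in filenames and provenance).
#' @param params A `model_params` object: the generating model.
#' @param tau Growth time / normalization time, years.
#' @param cohort_size Number of patients the noise level mimics (>= 1).
#' @param time_grid Years post-resection, all >= `tau`.
#' @param noise `"none"`, `"binomial"` (per-point sd
#'   `sqrt(f (1 - f) / cohort_size)`), or `"binomial+jitter"` (adds uniform
#'   digitization error of half-width `jitter_scale`).
#' @param jitter_scale Half-width of the uniform digitization jitter.
#' @return A `scenario` object.
#' @export
scenario <- function(name, params, tau, cohort_size, time_grid,
                     noise = c("none", "binomial", "binomial+jitter"),
                     jitter_scale = 0.005) {
  stopifnot(inherits(params, "model_params"))
  tau <- check_tau(tau)
  noise <- match.arg(noise)
  if (cohort_size < 1) stop("'cohort_size' must be >= 1", call. = FALSE)
  if (any(time_grid < tau)) {
    stop("'time_grid' must start at or after tau = ", tau, call. = FALSE)
  }
  structure(list(name = name, params = params, tau = tau,
                 cohort_size = as.integer(cohort_size),
                 time_grid = sort(as.numeric(time_grid)), noise = noise,
                 jitter_scale = jitter_scale),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario '", x$name, "': ", model_id(x$params), ", tau = ", x$tau,
      " y, n = ", x$cohort_size, ", noise = ", x$noise, ">\n", sep = "")
  invisible(x)
}

#' Generate a study-like KM RFI fixture
#'
#' Samples the scenario's closed-form RFI curve on its time grid, applies
#' the chosen noise, enforces monotonicity by a running minimum (a
#' digitized KM curve must be non-increasing), and re-normalizes at `tau`.
#' With `noise = "none"` the result equals the closed form exactly.
#'
#' @param scn A [scenario].
#' @param seed Optional integer seed.
#' @param path Optional file path; when given the curve is written as CSV
#'   ([write_rfi_csv()]) with a JSON provenance sidecar
#'   (`<path>.provenance.json`) recording scenario, parameters and seed.
#' @return An [rfi_curve] (invisibly when `path` is given).
#' @export
generate_km_fixture <- function(scn, seed = NULL, path = NULL) {
  stopifnot(inherits(scn, "scenario"))
  if (!is.null(seed)) set.seed(seed)
  f <- escape_survival(scn$params, scn$time_grid - scn$tau)
  if (scn$noise != "none") {
    f <- stats::rbinom(length(f), scn$cohort_size, f) / scn$cohort_size
    if (scn$noise == "binomial+jitter") {
      f <- f + stats::runif(length(f), -scn$jitter_scale, scn$jitter_scale)
    }
    f <- pmin(pmax(f, 0), 1)
    f <- cummin(f)                      # monotone correction
    f <- f / f[1]                       # re-normalize at tau
  }
  curve <- new_rfi_curve(scn$time_grid, f, tau = scn$tau)
  if (!is.null(path)) {
    write_rfi_csv(curve, path)
    prov <- list(scenario = scn$name, model = model_id(scn$params),
                 params = unclass(scn$params), tau = scn$tau,
                 cohort_size = scn$cohort_size, noise = scn$noise,
                 jitter_scale = scn$jitter_scale,
                 time_grid = scn$time_grid, seed = seed,
                 package_version = as.character(utils::packageVersion("dormancy")))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(curve))
  }
  curve
}

#' Preset synthetic scenarios
#'
#' Four named presets spanning the study conditions the generator emulates:
#'
#' * `ebctcg_like`: 15-year follow-up, 6399 patients, tau = 3 y, yearly
#'   grid 3-15 y, Zeroth model (monotone-decreasing hazard).
#' * `ebctcg_older_like`: same design with a slower escape rate.
#' * `chia_erpos_like`: 10-year follow-up, 1187 patients, tau = 1.5 y,
#'   half-yearly grid 1.5-10 y, Model 2 with almost no one-step
#'   micrometastases: its hazard has an interior maximum (the ER+ pattern).
#' * `chia_erneg_like`: same design, Zeroth model, monotone hazard.
#'
#' `zeroth_flat` is an alias of `ebctcg_like` retained as the canonical
#' non-peaked fixture name.
#'
#' @param noise Noise mode applied to every preset (default binomial).
#' @return Named list of [scenario] objects.
#' @export
preset_scenarios <- function(noise = "binomial") {
  ebctcg_grid <- seq(3, 15, by = 1)
  chia_grid <- seq(1.5, 10, by = 0.5)
  sc <- list(
    ebctcg_like = scenario("ebctcg_like",
                           zeroth_params(N_bar = 1, kappa = 0.1),
                           tau = 3, cohort_size = 6399,
                           time_grid = ebctcg_grid, noise = noise),
    ebctcg_older_like = scenario("ebctcg_older_like",
                                 zeroth_params(N_bar = 0.8, kappa = 0.06),
                                 tau = 3, cohort_size = 6399,
                                 time_grid = ebctcg_grid, noise = noise),
    chia_erpos_like = scenario("chia_erpos_like",
                               model2_params(N_s_bar = 1.5, N_V_bar = 0.05,
                                             kappa_s = 0.3, kappa_V = 0.25),
                               tau = 1.5, cohort_size = 1187,
                               time_grid = chia_grid, noise = noise),
    chia_erneg_like = scenario("chia_erneg_like",
                               zeroth_params(N_bar = 0.5, kappa = 0.15),
                               tau = 1.5, cohort_size = 1187,
                               time_grid = chia_grid, noise = noise))
  sc$zeroth_flat <- sc$ebctcg_like
  sc$zeroth_flat$name <- "zeroth_flat"
  sc
}
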