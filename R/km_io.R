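# RFI curve and hazard curve containers, CSV round-trip, normalization at
# the growth time tau, and hazard estimation/extrapolation from KM data.
#
# Time convention: files and curve objects use years post-resection; the
# escape clock is t = time - tau. Conversion happens only here and in
# rfi_curve().

#' Recurrence-free-interval curve objects
#'
#' An `rfi_curve` is a data.frame with columns `time_years` (strictly
#' increasing, years post-resection), `rfi` (recurrence-free fraction in
#' [0, 1]) and optionally `se` (Greenwood standard error) and `n_at_risk`.
#' The normalization time `tau` and a `normalized` flag are attributes.
#' Non-monotone input (as digitized curves can be) is accepted but flagged
#' via the `monotone` attribute.
#'
#' @param times Years post-resection, strictly increasing.
#' @param rfi Recurrence-free fractions in [0, 1].
#' @param tau Normalization (growth) time in years, or `NULL` if not yet
#'   normalized.
#' @param se,n_at_risk Optional per-point standard errors / numbers at risk.
#' @return An object of class `rfi_curve`.
#' @export
new_rfi_curve <- function(times, rfi, tau = NULL, se = NULL,
                          n_at_risk = NULL) {
  if (length(times) != length(rfi) || length(times) == 0L) {
    stop("'times' and 'rfi' must be non-empty and of equal length",
         call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (any(rfi < -1e-12) || any(rfi > 1 + 1e-12)) {
    stop("'rfi' values must lie in [0, 1]", call. = FALSE)
  }
  df <- data.frame(time_years = as.numeric(times),
                   rfi = pmin(pmax(as.numeric(rfi), 0), 1))
  if (!is.null(se)) df$se <- as.numeric(se)
  if (!is.null(n_at_risk)) df$n_at_risk <- as.numeric(n_at_risk)
  structure(df,
            class = c("rfi_curve", "data.frame"),
            tau = if (is.null(tau)) NULL else check_tau(tau),
            normalized = !is.null(tau) && abs(df$rfi[1] - 1) < 1e-12,
            monotone = !is.unsorted(rev(df$rfi)))
}

#' @export
print.rfi_curve <- function(x, ...) {
  tau <- attr(x, "tau")
  cat("<rfi_curve: ", nrow(x), " points, ",
      "t = [", min(x$time_years), ", ", max(x$time_years), "] y",
      if (!is.null(tau)) paste0(", tau = ", tau),
      if (!attr(x, "monotone")) ", NON-MONOTONE", ">\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n")
  invisible(x)
}

#' Read / write RFI curves as CSV
#'
#' Plain CSV with header `time_years,rfi` (optional `se`, `n_at_risk`
#' columns). The normalization time, when known, is stored in a leading
#' `# tau: <years>` comment line so the round-trip is lossless.
#'
#' @param path File path.
#' @return `read_rfi_csv` returns an [rfi_curve]; `write_rfi_csv` returns
#'   `path` invisibly.
#' @export
read_rfi_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  tau <- NULL
  hdr <- grep("^#", lines)
  for (i in hdr) {
    m <- regmatches(lines[i], regexec("^#\\s*tau:\\s*([0-9.eE+-]+)", lines[i]))[[1]]
    if (length(m) == 2) tau <- as.numeric(m[2])
  }
  df <- utils::read.csv(text = lines, comment.char = "#",
                        stringsAsFactors = FALSE)
  for (col in c("time_years", "rfi")) {
    if (!col %in% names(df)) {
      stop("missing required column '", col, "' in ", path, call. = FALSE)
    }
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad <- which(!is.finite(df$time_years) | !is.finite(df$rfi))
  if (length(bad)) {
    stop("malformed (non-numeric) rows in ", path, " at data line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  new_rfi_curve(df$time_years, df$rfi, tau = tau, se = df$se,
                n_at_risk = df$n_at_risk)
}

#' @rdname read_rfi_csv
#' @param curve An [rfi_curve].
#' @export
write_rfi_csv <- function(curve, path) {
  stopifnot(inherits(curve, "rfi_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  tau <- attr(curve, "tau")
  if (!is.null(tau)) writeLines(paste0("# tau: ", format(tau, digits = 17)), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' Normalize an RFI curve at the growth time tau
#'
#' Restricting the curve to times at or beyond tau excludes patients who
#' already had growing or detectable metastases at resection. Points before
#' `tau` are dropped, `f(tau)` is obtained by linear interpolation when
#' `tau` falls between grid points, the remaining values are divided by
#' `f(tau)`, and the curve's first point becomes `(tau, 1)`.
#'
#' @param curve An [rfi_curve].
#' @param tau Growth time in years; must lie within the curve's time span.
#' @return A normalized [rfi_curve].
#' @export
normalize_at_tau <- function(curve, tau) {
  stopifnot(inherits(curve, "rfi_curve"))
  tau <- check_tau(tau)
  tm <- curve$time_years
  if (tau > tm[length(tm)]) {
    stop("tau = ", tau, " lies beyond the last curve point (",
         tm[length(tm)], " years)", call. = FALSE)
  }
  f_tau <- if (tau <= tm[1]) curve$rfi[1] else
    stats::approx(tm, curve$rfi, xout = tau)$y
  if (f_tau <= 0) stop("rfi at tau is non-positive; cannot normalize",
                       call. = FALSE)
  keep <- tm > tau + 1e-12
  times <- c(tau, tm[keep])
  rfi <- c(1, curve$rfi[keep] / f_tau)
  new_rfi_curve(times, pmin(rfi, 1), tau = tau)
}

#' Hazard curve objects
#'
#' A `hazard_curve` is a data.frame with columns `time_years` (years
#' post-resection), `h` (hazard in 1/year, >= 0) and `extrapolated`
#' (logical). Smoothing and extrapolation metadata are kept in attributes.
#'
#' @name hazard_curve
NULL

new_hazard_curve <- function(times, h, extrapolated = FALSE, tau = NULL,
                             smoothing = list(method = "none"),
                             extrapolation = NULL, floored = FALSE) {
  df <- data.frame(time_years = as.numeric(times), h = as.numeric(h),
                   extrapolated = rep_len(extrapolated, length(times)))
  structure(df, class = c("hazard_curve", "data.frame"), tau = tau,
            smoothing = smoothing, extrapolation = extrapolation,
            floored = floored)
}

#' @export
print.hazard_curve <- function(x, ...) {
  sm <- attr(x, "smoothing")
  cat("<hazard_curve: ", nrow(x), " points, smoothing = ", sm$method,
      if (any(x$extrapolated)) paste0(", ", sum(x$extrapolated),
                                      " extrapolated"),
      ">\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n")
  invisible(x)
}

#' Estimate a hazard curve from a normalized RFI curve
#'
#' Life-table style estimate: over each bin the hazard is
#' `-(log f(right) - log f(left)) / bin width`, placed at the bin midpoint.
#' The default bin width is the data spacing. Optional Gaussian-kernel
#' smoothing (default bandwidth 1 year) replaces each value with the
#' kernel-weighted average of the raw bin values. Negative finite
#' differences (possible in noisy digitized curves after monotone
#' correction edge cases) are floored at 0 and flagged.
#'
#' @param curve A normalized [rfi_curve] with strictly positive `rfi`.
#' @param bin_width Bin width in years; `NULL` uses consecutive grid points.
#' @param smooth Logical: apply Gaussian kernel smoothing.
#' @param bandwidth Kernel bandwidth in years.
#' @return A [hazard_curve].
#' @export
hazard_from_km <- function(curve, bin_width = NULL, smooth = FALSE,
                           bandwidth = 1) {
  stopifnot(inherits(curve, "rfi_curve"))
  if (!isTRUE(attr(curve, "normalized"))) {
    stop("curve must be normalized at tau first (see normalize_at_tau())",
         call. = FALSE)
  }
  if (any(curve$rfi <= 0)) {
    stop("rfi values must be strictly positive to take logs", call. = FALSE)
  }
  tm <- curve$time_years
  f <- curve$rfi
  if (!is.null(bin_width)) {
    spacing <- min(diff(tm))
    if (bin_width < spacing - 1e-9) {
      stop("bin_width must be >= the grid spacing (", spacing, " years)",
           call. = FALSE)
    }
    edges <- seq(tm[1], tm[length(tm)], by = bin_width)
    if (edges[length(edges)] < tm[length(tm)] - 1e-9) {
      edges <- c(edges, tm[length(tm)])
    }
    f_e <- stats::approx(tm, f, xout = edges)$y
    tm <- edges; f <- f_e
  }
  dlf <- diff(log(f))
  dt <- diff(tm)
  h_raw <- -dlf / dt
  floored <- any(h_raw < 0)
  h <- pmax(h_raw, 0)
  mid <- (tm[-1] + tm[-length(tm)]) / 2
  smoothing <- list(method = "none", bin_width = bin_width)
  if (smooth) {
    w <- outer(mid, mid, function(a, b) stats::dnorm(a - b, sd = bandwidth))
    h <- as.numeric(w %*% h / rowSums(w))
    smoothing <- list(method = "gaussian_kernel", bandwidth = bandwidth,
                      bin_width = bin_width)
  }
  new_hazard_curve(mid, h, tau = attr(curve, "tau"), smoothing = smoothing,
                   floored = floored)
}

#' Extrapolate a hazard curve beyond its data range
#'
#' Long-horizon burden estimation needs hazards beyond follow-up (e.g. up
#' to 20 years post-resection). Two tail rules: `"constant"` (default)
#' holds the last observed value; `"loglinear"` fits `log h` linearly on
#' the tail of the observed points and extends that exponential decay.
#' Extrapolated points are flagged.
#'
#' @param hc A [hazard_curve].
#' @param t_end Target end time (years post-resection). If not beyond the
#'   data, the input is returned unchanged.
#' @param rule `"constant"` or `"loglinear"`.
#' @param tail_points Number of trailing observed points used by the
#'   log-linear fit (default: half of them, at least 3).
#' @return A [hazard_curve] including the extrapolated points.
#' @export
extrapolate_hazard <- function(hc, t_end, rule = c("constant", "loglinear"),
                               tail_points = NULL) {
  stopifnot(inherits(hc, "hazard_curve"))
  rule <- match.arg(rule)
  obs <- hc[!hc$extrapolated, ]
  t_last <- max(obs$time_years)
  if (t_end <= t_last) return(hc)
  spacing <- if (nrow(obs) > 1) min(diff(obs$time_years)) else 1
  t_new <- seq(t_last + spacing, t_end, by = spacing)
  if (t_new[length(t_new)] < t_end - 1e-9) t_new <- c(t_new, t_end)
  h_new <- if (rule == "constant") {
    rep(obs$h[nrow(obs)], length(t_new))
  } else {
    if (is.null(tail_points)) tail_points <- max(3L, nrow(obs) %/% 2L)
    tail_df <- utils::tail(obs, tail_points)
    if (any(tail_df$h <= 0)) {
      stop("log-linear extrapolation requires positive tail hazards",
           call. = FALSE)
    }
    fit <- stats::lm(log(h) ~ time_years, data = tail_df)
    exp(stats::predict(fit, newdata = data.frame(time_years = t_new)))
  }
  new_hazard_curve(c(obs$time_years, t_new), c(obs$h, h_new),
                   extrapolated = c(rep(FALSE, nrow(obs)),
                                    rep(TRUE, length(t_new))),
                   tau = attr(hc, "tau"), smoothing = attr(hc, "smoothing"),
                   extrapolation = list(rule = rule, t_end = t_end),
                   floored = attr(hc, "floored"))
}
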