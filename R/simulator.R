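# Exact event-driven stochastic simulation of patients and cohorts under the
# four dormancy models. Micrometastasis lineages are independent given the
# initial counts, so everything except Model 1's permissive (branching)
# lineages is sampled in closed form per lineage; permissive lineages run a
# Gillespie loop. All clocks are years post-resection; a patient relapses at
# first escape + tau.

EVENT_CAP <- 1e6L

# Gillespie simulation of one permissive Model-1 lineage (birth mu, death
# lam, escape kappa) started from one micrometastasis.
# Returns list(escape_time, alive_at_horizon). escape_time is Inf when the
# lineage goes extinct (or survives the horizon) without an escape.
sim_perm_lineage <- function(kappa, lam, mu, horizon = Inf,
                             cap = EVENT_CAP) {
  n <- 1L
  tt <- 0
  total <- kappa + lam + mu
  if (total <= 0) {
    return(list(escape_time = Inf, alive_at_horizon = 1L))
  }
  p_birth <- mu / total
  p_death <- (mu + lam) / total
  for (i in seq_len(cap)) {
    if (n == 0L) return(list(escape_time = Inf, alive_at_horizon = 0L))
    tt <- tt + stats::rexp(1L, rate = n * total)
    if (tt > horizon) return(list(escape_time = Inf, alive_at_horizon = n))
    u <- stats::runif(1L)
    if (u < p_birth) {
      n <- n + 1L
    } else if (u < p_death) {
      n <- n - 1L
    } else {
      return(list(escape_time = tt, alive_at_horizon = NA_integer_))
    }
  }
  stop("event cap (", cap, " events) exceeded in a permissive lineage; ",
       "the seeding process is likely supercritical (mu > lam + kappa)",
       call. = FALSE)
}

# First escape time (years post-resection) for one patient, plus clearance.
# Used by simulate_patient() and, vectorized model-by-model, by
# simulate_cohort().
patient_escape <- function(params, init_count = NULL) {
  P <- plist(params)
  switch(model_id(params),
    zeroth = {
      N <- if (is.null(init_count)) stats::rpois(1L, P$N_bar) else init_count
      esc <- if (N == 0L || P$kappa <= 0) Inf else
        stats::rexp(1L, rate = N * P$kappa)
      list(escape = esc, cleared = N == 0L)
    },
    model3 = {
      N <- if (is.null(init_count)) stats::rpois(1L, P$N_bar) else init_count
      esc <- if (N == 0L) Inf else inv_cdf_linear_rate(
        stats::rexp(1L) / N, P$a, P$b)
      list(escape = esc, cleared = N == 0L)
    },
    model2 = {
      nV <- stats::rpois(1L, P$N_V_bar)
      ns <- stats::rpois(1L, P$N_s_bar)
      t_V <- if (nV == 0L || P$kappa_V <= 0) Inf else
        stats::rexp(1L, rate = nV * P$kappa_V)
      t_s <- Inf
      if (ns > 0L && P$kappa_s > 0 && P$kappa_V > 0) {
        t_s <- min(stats::rexp(ns, P$kappa_s) + stats::rexp(ns, P$kappa_V))
      }
      list(escape = min(t_V, t_s), cleared = nV + ns == 0L)
    },
    model1 = {
      n_perm <- stats::rpois(1L, P$N_bar * P$p_M)
      n_np <- stats::rpois(1L, P$N_bar * (1 - P$p_M))
      esc <- Inf
      all_gone <- TRUE
      # non-permissive: competing exponentials, event type independent of time
      s <- P$kappa + P$lam
      if (n_np > 0L) {
        if (s <= 0) {
          all_gone <- FALSE         # inert micrometastases persist forever
        } else {
          # every lineage eventually has an event: escape w.p. kappa/s,
          # otherwise it disappears
          ev_t <- stats::rexp(n_np, s)
          is_esc <- stats::runif(n_np) < P$kappa / s
          if (any(is_esc)) esc <- min(esc, min(ev_t[is_esc]))
        }
      }
      if (n_perm > 0L) {
        for (j in seq_len(n_perm)) {
          lin <- sim_perm_lineage(P$kappa, P$lam, P$mu)
          if (is.finite(lin$escape_time)) {
            esc <- min(esc, lin$escape_time)
          } else if (lin$alive_at_horizon > 0L) {
            all_gone <- FALSE       # inert lineage persists
          }
        }
      }
      list(escape = esc, cleared = is.infinite(esc) && all_gone)
    })
}

# Inverse CDF of the first-event time under the linear rate a + b t:
# solves a t + b t^2 / 2 = e for t >= 0.
inv_cdf_linear_rate <- function(e, a, b) {
  if (a <= 0 && b <= 0) return(Inf)
  if (b <= 0) return(e / a)
  (-a + sqrt(a^2 + 2 * b * e)) / b
}

#' Simulate a single patient
#'
#' Draws the initial micrometastasis count(s) from their Poisson
#' distributions and runs the model's continuous-time Markov dynamics
#' exactly (competing exponentials; inverse-CDF sampling for Model 3's
#' time-inhomogeneous escape; Gillespie for Model 1's seeding lineages).
#' The patient relapses at first escape + `tau`.
#'
#' @param params A `model_params` object.
#' @param tau Growth time, years (> 0).
#' @param seed Optional integer seed (set locally for reproducibility).
#' @return A list with `relapse_time` (years post-resection, `Inf` if
#'   never), `first_escape_time` (= `relapse_time - tau`), and `cleared`
#'   (all micrometastases disappeared / none existed).
#' @export
simulate_patient <- function(params, tau, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  tau <- check_tau(tau)
  if (!is.null(seed)) set.seed(seed)
  out <- patient_escape(params)
  list(relapse_time = out$escape + tau,
       first_escape_time = out$escape,
       cleared = out$cleared)
}

check_censoring <- function(censoring) {
  if (is.null(censoring)) censoring <- list(type = "none")
  if (is.character(censoring)) censoring <- list(type = censoring)
  if (!is.list(censoring) || is.null(censoring$type) ||
      !censoring$type %in% c("none", "administrative", "uniform_entry")) {
    stop("censoring spec must be one of: list(type = \"none\"), ",
         "list(type = \"administrative\", T_end = ), ",
         "list(type = \"uniform_entry\", T_accrual = , T_end = )",
         call. = FALSE)
  }
  if (censoring$type == "administrative" &&
      !(is.numeric(censoring$T_end) && censoring$T_end > 0)) {
    stop("administrative censoring needs a positive 'T_end'", call. = FALSE)
  }
  if (censoring$type == "uniform_entry" &&
      !(is.numeric(censoring$T_end) && is.numeric(censoring$T_accrual) &&
        censoring$T_end > censoring$T_accrual && censoring$T_accrual >= 0)) {
    stop("uniform-entry censoring needs 0 <= T_accrual < T_end",
         call. = FALSE)
  }
  censoring
}

draw_kappa <- function(n, kappa_dist) {
  switch(kappa_dist$type,
    gamma = stats::rgamma(n, shape = kappa_dist$shape,
                          rate = kappa_dist$shape / kappa_dist$mean),
    two_point = sample(kappa_dist$values, n, replace = TRUE,
                       prob = kappa_dist$prob),
    stop("kappa_dist$type must be 'gamma' or 'two_point'", call. = FALSE))
}

draw_counts <- function(n, N_bar, count_dist = NULL) {
  if (is.null(count_dist)) return(stats::rpois(n, N_bar))
  switch(count_dist$type,
    poisson = stats::rpois(n, count_dist$mean),
    fixed = rep.int(as.integer(count_dist$n), n),
    mixture = sample(as.integer(count_dist$n), n, replace = TRUE,
                     prob = count_dist$prob),
    stop("unknown count distribution type", call. = FALSE))
}

#' Simulate a patient cohort into an event table
#'
#' Vectorized exact simulation of `n_patients` independent patients, with
#' optional censoring. Lineages are sampled in closed form wherever the
#' model permits (all of the Zeroth model, Models 2-3, and Model 1's
#' non-permissive lineages); Model 1's permissive lineages run Gillespie.
#'
#' @param n_patients Number of patients (>= 1).
#' @param params A `model_params` object.
#' @param tau Growth time, years.
#' @param censoring `list(type = "none")` (default; non-relapsing patients
#'   carry `time_years = Inf`), `list(type = "administrative", T_end = )`,
#'   or `list(type = "uniform_entry", T_accrual = , T_end = )` (staggered
#'   entry: follow-up `T_end - entry`, entry ~ U(0, T_accrual)).
#' @param seed Optional integer seed.
#' @param count_dist Zeroth model only: override the Poisson initial-count
#'   distribution (`list(type = "fixed", n = )`,
#'   `list(type = "mixture", n = , prob = )`).
#' @param kappa_dist Zeroth model only: per-patient escape-rate
#'   heterogeneity (`list(type = "gamma", mean = , shape = )` or
#'   `list(type = "two_point", values = , prob = )`); overrides `kappa`.
#' @return An `event_table`: data.frame with `patient_id`, `time_years`
#'   (observed time post-resection) and `event` (`"relapse"`/`"censored"`).
#' @export
simulate_cohort <- function(n_patients, params, tau,
                            censoring = list(type = "none"), seed = NULL,
                            count_dist = NULL, kappa_dist = NULL) {
  stopifnot(inherits(params, "model_params"),
            length(n_patients) == 1L, n_patients >= 1)
  n_patients <- as.integer(n_patients)
  tau <- check_tau(tau)
  censoring <- check_censoring(censoring)
  if (!is.null(seed)) set.seed(seed)
  if ((!is.null(count_dist) || !is.null(kappa_dist)) &&
      model_id(params) != "zeroth") {
    stop("'count_dist' and 'kappa_dist' are supported for the Zeroth model",
         call. = FALSE)
  }
  esc <- cohort_escape_times(n_patients, params, count_dist, kappa_dist)
  relapse <- esc + tau
  cens_time <- switch(censoring$type,
    none = rep(Inf, n_patients),
    administrative = rep(censoring$T_end, n_patients),
    uniform_entry = censoring$T_end -
      stats::runif(n_patients, 0, censoring$T_accrual))
  observed <- pmin(relapse, cens_time)
  event <- ifelse(relapse <= cens_time & is.finite(relapse),
                  "relapse", "censored")
  structure(data.frame(patient_id = seq_len(n_patients),
                       time_years = observed, event = event,
                       stringsAsFactors = FALSE),
            class = c("event_table", "data.frame"))
}

# Vectorized first-escape times (years post-resection) for a cohort.
cohort_escape_times <- function(n, params, count_dist = NULL,
                                kappa_dist = NULL) {
  P <- plist(params)
  model <- model_id(params)
  if (model == "zeroth") {
    N <- draw_counts(n, P$N_bar, count_dist)
    kap <- if (is.null(kappa_dist)) rep(P$kappa, n) else
      draw_kappa(n, kappa_dist)
    esc <- rep(Inf, n)
    act <- N > 0L & kap > 0
    esc[act] <- stats::rexp(sum(act), rate = N[act] * kap[act])
    return(esc)
  }
  if (model == "model3") {
    N <- stats::rpois(n, P$N_bar)
    esc <- rep(Inf, n)
    act <- N > 0L & (P$a > 0 || P$b > 0)
    if (any(act)) {
      e <- stats::rexp(sum(act)) / N[act]
      esc[act] <- if (P$b <= 0) e / P$a else
        (-P$a + sqrt(P$a^2 + 2 * P$b * e)) / P$b
    }
    return(esc)
  }
  if (model == "model2") {
    nV <- stats::rpois(n, P$N_V_bar)
    ns <- stats::rpois(n, P$N_s_bar)
    esc <- rep(Inf, n)
    act <- nV > 0L & P$kappa_V > 0
    esc[act] <- stats::rexp(sum(act), rate = nV[act] * P$kappa_V)
    if (P$kappa_s > 0 && P$kappa_V > 0 && any(ns > 0L)) {
      pid <- rep.int(seq_len(n), ns)
      m <- length(pid)
      if (m > 0) {
        lin <- stats::rexp(m, P$kappa_s) + stats::rexp(m, P$kappa_V)
        t_s <- vapply(split(lin, pid), min, numeric(1))
        ids <- as.integer(names(t_s))
        esc[ids] <- pmin(esc[ids], t_s)
      }
    }
    return(esc)
  }
  # model1
  esc <- rep(Inf, n)
  s <- P$kappa + P$lam
  n_np <- stats::rpois(n, P$N_bar * (1 - P$p_M))
  if (s > 0 && any(n_np > 0L)) {
    # each non-permissive lineage escapes (rather than disappears) with
    # probability kappa / (kappa + lam); escape times are then iid Exp(s)
    n_esc <- stats::rbinom(n, n_np, P$kappa / s)
    act <- n_esc > 0L
    esc[act] <- stats::rexp(sum(act), rate = n_esc[act] * s)
  }
  n_perm <- stats::rpois(n, P$N_bar * P$p_M)
  for (i in which(n_perm > 0L)) {
    for (j in seq_len(n_perm[i])) {
      lin <- sim_perm_lineage(P$kappa, P$lam, P$mu, horizon = esc[i])
      if (is.finite(lin$escape_time)) {
        esc[i] <- min(esc[i], lin$escape_time)
      }
    }
  }
  esc
}

#' Kaplan-Meier RFI curve from an event table
#'
#' Product-limit estimator with Greenwood standard errors, via
#' [survival::survfit()]. Non-relapsing patients recorded with infinite
#' observation time (uncensored follow-up) are treated as censored after
#' the last event, which leaves the estimator unchanged.
#'
#' @param event_table An event table from [simulate_cohort()] (columns
#'   `patient_id`, `time_years`, `event`).
#' @return An [rfi_curve] evaluated at the event times, with `se` and
#'   `n_at_risk` columns.
#' @export
km_estimate <- function(event_table) {
  if (!is.data.frame(event_table) || nrow(event_table) == 0L) {
    stop("event table must be a non-empty data.frame", call. = FALSE)
  }
  for (col in c("time_years", "event")) {
    if (!col %in% names(event_table)) {
      stop("event table lacks column '", col, "'", call. = FALSE)
    }
  }
  tm <- event_table$time_years
  status <- as.integer(event_table$event == "relapse")
  finite_max <- if (any(is.finite(tm))) max(tm[is.finite(tm)]) else 1
  tm[!is.finite(tm)] <- finite_max + 1
  fit <- survival::survfit(survival::Surv(tm, status) ~ 1)
  keep <- fit$n.event > 0
  if (!any(keep)) {
    # all censored: S = 1 throughout
    return(new_rfi_curve(times = max(tm), rfi = 1, se = 0,
                         n_at_risk = length(tm)))
  }
  new_rfi_curve(times = fit$time[keep], rfi = fit$surv[keep],
                se = fit$surv[keep] * fit$std.err[keep],
                n_at_risk = fit$n.risk[keep])
}

#' Write / read event tables as CSV
#' @param event_table An event table.
#' @param path File path.
#' @return The path (write) or an `event_table` (read).
#' @export
write_event_csv <- function(event_table, path) {
  utils::write.csv(as.data.frame(event_table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("patient_id", "time_years", "event")) {
    if (!col %in% names(df)) {
      stop("missing required column '", col, "' in ", path, call. = FALSE)
    }
  }
  structure(df, class = c("event_table", "data.frame"))
}

#' Conditioned (killed-process) ensemble moments
#'
#' Simulates `n_reps` patients, keeps those with no escape by escape-clock
#' time `t`, and returns the empirical per-type micrometastasis count
#' moments with standard errors. This is the simulation oracle for
#' [conditional_moments()] and for the hazard-derivative decomposition.
#'
#' @param params A `model_params` object.
#' @param t Conditioning time (years, escape clock).
#' @param n_reps Number of simulated patients; at least 100 must survive
#'   the conditioning or an error is raised (conditioning starvation).
#' @param seed Optional integer seed.
#' @return A list with `n_surviving`, `mean`, `var`, `se_mean` (named per
#'   type), and `counts` (matrix of per-rep conditioned counts, one column
#'   per type).
#' @export
conditioned_ensemble <- function(params, t, n_reps, seed = NULL) {
  stopifnot(inherits(params, "model_params"), length(t) == 1L, n_reps >= 1)
  t <- check_time(t)
  if (!is.null(seed)) set.seed(seed)
  P <- plist(params)
  counts <- switch(model_id(params),
    zeroth = {
      N <- stats::rpois(n_reps, P$N_bar)
      n_esc <- stats::rbinom(n_reps, N, 1 - exp(-P$kappa * t))
      cbind(micrometastasis = N[n_esc == 0L])
    },
    model3 = {
      N <- stats::rpois(n_reps, P$N_bar)
      n_esc <- stats::rbinom(n_reps, N, 1 - q_model3(t, P$a, P$b))
      cbind(micrometastasis = N[n_esc == 0L])
    },
    model2 = {
      nV0 <- stats::rpois(n_reps, P$N_V_bar)
      ns0 <- stats::rpois(n_reps, P$N_s_bar)
      escV <- stats::rbinom(n_reps, nV0, 1 - exp(-P$kappa_V * t))
      p_ss <- exp(-P$kappa_s * t)
      p_noesc <- q_two_stage(t, P$kappa_s, P$kappa_V)
      esc_s <- stats::rbinom(n_reps, ns0, 1 - p_noesc)
      still_s <- stats::rbinom(n_reps, ns0 - esc_s, p_ss / p_noesc)
      ok <- escV + esc_s == 0L
      cbind(s = still_s[ok], V = nV0[ok] + (ns0 - still_s)[ok])
    },
    model1 = {
      s <- P$kappa + P$lam
      n_np0 <- stats::rpois(n_reps, P$N_bar * (1 - P$p_M))
      if (s > 0) {
        ev <- stats::rbinom(n_reps, n_np0, 1 - exp(-s * t))
        esc_np <- stats::rbinom(n_reps, ev, P$kappa / s)
        np_alive <- n_np0 - ev
      } else {
        esc_np <- integer(n_reps)
        np_alive <- n_np0
      }
      n_p0 <- stats::rpois(n_reps, P$N_bar * P$p_M)
      p_alive <- integer(n_reps)
      esc_p <- logical(n_reps)
      for (i in which(n_p0 > 0L)) {
        tot <- 0L
        for (j in seq_len(n_p0[i])) {
          lin <- sim_perm_lineage(P$kappa, P$lam, P$mu, horizon = t)
          if (is.finite(lin$escape_time)) { esc_p[i] <- TRUE; break }
          tot <- tot + lin$alive_at_horizon
        }
        p_alive[i] <- tot
      }
      ok <- esc_np == 0L & !esc_p
      cbind(non_permissive = np_alive[ok], permissive = p_alive[ok])
    })
  m <- nrow(counts)
  if (m < 100L) {
    stop("conditioning starvation: only ", m, " of ", n_reps,
         " simulated patients had no escape by t = ", t,
         "; increase n_reps", call. = FALSE)
  }
  means <- colMeans(counts)
  vars <- apply(counts, 2, stats::var)
  list(n_surviving = m, mean = means, var = vars,
       se_mean = sqrt(vars / m), counts = counts)
}
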