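# Closed-form per-lineage no-escape probabilities, Poisson-mixed survival,
# hazards and conditioned moments for the four dormancy models.
#
# Convention: all functions here run on the escape clock t (years since
# resection minus the growth time tau). Time post-resection is t + tau;
# rfi_curve() does the conversion.

# -- per-lineage no-escape probabilities (vectorized over t and parameters) --

q_zeroth <- function(t, kappa) exp(-kappa * t)

q_model3 <- function(t, a, b) exp(-(a * t + b * t^2 / 2))

# Two-stage lineage: s -> V at kappa_s, then escape at kappa_V.
# No-escape probability = survival of a hypoexponential(kappa_s, kappa_V)
# waiting time; the equal-rate limit is the Erlang(2) survival.
q_two_stage <- function(t, kappa_s, kappa_V) {
  n <- max(length(t), length(kappa_s), length(kappa_V))
  t <- rep_len(t, n); ks <- rep_len(kappa_s, n); kv <- rep_len(kappa_V, n)
  d <- ks - kv
  near <- abs(d) <= 1e-9 * (1 + ks + kv)
  out <- numeric(n)
  if (any(!near)) {
    i <- !near
    out[i] <- exp(-ks[i] * t[i]) +
      ks[i] * (exp(-kv[i] * t[i]) - exp(-ks[i] * t[i])) / d[i]
  }
  if (any(near)) {
    i <- near
    k <- (ks[i] + kv[i]) / 2
    out[i] <- exp(-k * t[i]) * (1 + k * t[i])
  }
  out
}

# Non-permissive Model-1 lineage: escape (kappa) vs disappearance (lam),
# no seeding. No-escape probability from competing exponentials.
q_nonperm <- function(t, kappa, lam) {
  n <- max(length(t), length(kappa), length(lam))
  t <- rep_len(t, n); k <- rep_len(kappa, n); l <- rep_len(lam, n)
  s <- k + l
  out <- rep_len(1, n)
  pos <- s > 0
  out[pos] <- (l[pos] + k[pos] * exp(-s[pos] * t[pos])) / s[pos]
  out
}

# Riccati roots for the permissive Model-1 lineage (birth mu, death lam,
# escape kappa): mu x^2 - (mu+lam+kappa) x + lam = 0. With kappa > 0 the
# roots straddle 1 (r1 < 1 < r2).
riccati_roots <- function(kappa, lam, mu) {
  s <- mu + lam + kappa
  disc <- sqrt(pmax(s^2 - 4 * mu * lam, 0))
  list(r1 = (s - disc) / (2 * mu), r2 = (s + disc) / (2 * mu), disc = disc)
}

# Permissive Model-1 lineage no-escape probability q_M(t): solution of the
# backward equation q' = mu q^2 - (mu+lam+kappa) q + lam, q(0) = 1.
q_perm <- function(t, kappa, lam, mu) {
  n <- max(length(t), length(kappa), length(lam), length(mu))
  t <- rep_len(t, n); k <- rep_len(kappa, n)
  l <- rep_len(lam, n); m <- rep_len(mu, n)
  out <- numeric(n)
  nok <- k <= 0                      # no escape channel: q = 1
  nom <- !nok & m <= 1e-14           # no seeding: linear ODE, competing exp
  gen <- !nok & !nom
  out[nok] <- 1
  if (any(nom)) out[nom] <- q_nonperm(t[nom], k[nom], l[nom])
  if (any(gen)) {
    rt <- riccati_roots(k[gen], l[gen], m[gen])
    C <- (1 - rt$r1) / (1 - rt$r2)   # negative since r1 < 1 < r2
    A <- C * exp(-rt$disc * t[gen])
    out[gen] <- (rt$r1 - rt$r2 * A) / (1 - A)
  }
  out
}

# -log escape survival, vectorized over t and over parameter vectors in P.
neg_log_surv <- function(model, t, P) {
  switch(model,
    zeroth = P$N_bar * (1 - q_zeroth(t, P$kappa)),
    model1 = P$N_bar * (P$p_M * (1 - q_perm(t, P$kappa, P$lam, P$mu)) +
               (1 - P$p_M) * (1 - q_nonperm(t, P$kappa, P$lam))),
    model2 = P$N_V_bar * (1 - q_zeroth(t, P$kappa_V)) +
             P$N_s_bar * (1 - q_two_stage(t, P$kappa_s, P$kappa_V)),
    model3 = P$N_bar * (1 - q_model3(t, P$a, P$b)),
    stop("unknown model '", model, "'"))
}

esc_surv <- function(model, t, P) {
  # clamp away one-ulp excursions from the Riccati/limit branches
  pmin(pmax(exp(-neg_log_surv(model, t, P)), 0), 1)
}

# Analytic hazard h(t) = -d log S / dt, vectorized like neg_log_surv().
hazard_analytic <- function(model, t, P) {
  switch(model,
    zeroth = P$N_bar * P$kappa * exp(-P$kappa * t),
    model1 = {
      q <- q_perm(t, P$kappa, P$lam, P$mu)
      s <- P$mu + P$lam + P$kappa
      # -q' from the backward equation; also valid at mu = 0
      neg_qp <- -(P$mu * q^2 - s * q + P$lam)
      P$N_bar * (P$p_M * neg_qp +
                 (1 - P$p_M) * P$kappa * exp(-(P$lam + P$kappa) * t))
    },
    model2 = {
      n <- max(length(t), length(P$kappa_s), length(P$kappa_V),
               length(P$N_s_bar), length(P$N_V_bar))
      t2 <- rep_len(t, n)
      ks <- rep_len(P$kappa_s, n); kv <- rep_len(P$kappa_V, n)
      d <- ks - kv
      near <- abs(d) <= 1e-9 * (1 + ks + kv)
      dens <- numeric(n)
      i <- !near
      dens[i] <- ks[i] * kv[i] * (exp(-kv[i] * t2[i]) - exp(-ks[i] * t2[i])) / d[i]
      if (any(near)) {
        k <- (ks[near] + kv[near]) / 2
        dens[near] <- k^2 * t2[near] * exp(-k * t2[near])
      }
      rep_len(P$N_V_bar, n) * kv * exp(-kv * t2) + rep_len(P$N_s_bar, n) * dens
    },
    model3 = P$N_bar * (P$a + P$b * t) * q_model3(t, P$a, P$b),
    stop("unknown model '", model, "'"))
}

plist <- function(params) unclass(params)

#' Probability that no micrometastasis has escaped by escape-clock time t
#'
#' The patient-level no-escape (dormancy survival) probability, mixed over
#' Poisson-distributed initial micrometastasis counts. A patient relapses at
#' time `t + tau` post-resection when the first escape happens at
#' escape-clock time `t`, so this function is the model RFI curve expressed
#' on the escape clock.
#'
#' @param params A `model_params` object.
#' @param t Escape-clock time(s) in years, >= 0 (vectorized).
#' @return Numeric vector of probabilities in [0, 1], equal to 1 at `t = 0`
#'   and non-increasing in `t`.
#' @seealso [rfi_curve()], [hazard_rate()], [relapse_rate()]
#' @export
escape_survival <- function(params, t) {
  stopifnot(inherits(params, "model_params"))
  t <- check_time(t)
  esc_surv(model_id(params), t, plist(params))
}

#' Model hazard rate on the escape clock
#'
#' The relapse hazard among patients recurrence-free at time `t + tau`
#' post-resection, `h = -d log f / dt`, computed from the analytic
#' derivative of the closed-form survival.
#'
#' @inheritParams escape_survival
#' @return Hazard rate(s) in 1/year, >= 0.
#' @export
hazard_rate <- function(params, t) {
  stopifnot(inherits(params, "model_params"))
  t <- check_time(t)
  pmax(hazard_analytic(model_id(params), t, plist(params)), 0)
}

#' Model relapse rate (density of relapse times)
#'
#' `r(t + tau) = h(t + tau) * f(t + tau)`: the unconditional rate at which
#' patients relapse, integrating over t to the total relapse probability.
#'
#' @inheritParams escape_survival
#' @return Density value(s) in 1/year.
#' @export
relapse_rate <- function(params, t) {
  hazard_rate(params, t) * escape_survival(params, t)
}

#' Numeric derivative of the model hazard
#'
#' Adaptive central difference with one step of Richardson extrapolation on
#' the analytic hazard; falls back to a second-order forward difference when
#' `t` is too close to 0 for a central stencil.
#'
#' @inheritParams escape_survival
#' @param t Single escape-clock time, >= 0.
#' @return dh/dt in 1/year^2.
#' @export
hazard_derivative <- function(params, t) {
  stopifnot(inherits(params, "model_params"), length(t) == 1L)
  t <- check_time(t)
  h <- function(x) hazard_rate(params, x)
  step <- max(1e-5, 1e-5 * t)
  if (t >= 2 * step) {
    cd <- function(s) (h(t + s) - h(t - s)) / (2 * s)
    (4 * cd(step / 2) - cd(step)) / 3
  } else {
    fd <- function(s) (-3 * h(t) + 4 * h(t + s) - h(t + 2 * s)) / (2 * s)
    (4 * fd(step / 2) - fd(step)) / 3
  }
}

#' Closed-form model RFI curve on a post-resection time grid
#'
#' Evaluates the model recurrence-free fraction normalized at the growth
#' time `tau`: `f_tau(t + tau) = escape_survival(t)`, so the curve equals 1
#' at `tau` and is non-increasing.
#'
#' @param params A `model_params` object.
#' @param times Times post-resection in years, all >= `tau`, strictly
#'   increasing.
#' @param tau Growth time in years (> 0): the lag between a
#'   micrometastasis's escape and clinical detectability.
#' @return An [rfi_curve] object.
#' @export
rfi_curve <- function(params, times, tau) {
  tau <- check_tau(tau)
  if (any(times < tau)) {
    stop("all 'times' must be >= tau = ", tau, " (years post-resection)",
         call. = FALSE)
  }
  new_rfi_curve(times = times, rfi = escape_survival(params, times - tau),
                tau = tau)
}

#' Conditioned micrometastasis count moments
#'
#' Mean and variance of the per-type micrometastasis counts at escape-clock
#' time `t` among patients with no escape by `t` (the killed process). For
#' the Zeroth model and Models 2-3 the conditioned counts are independent
#' Poisson by the colouring (thinning) property; for Model 1's permissive
#' lineages the moments come from the lineage generating function: the
#' conditioned mean factor is
#' `G(t) = exp(2 mu Int q_M ds - (mu+lam+kappa) t)` (closed form) and the
#' second factorial moment uses one numerical quadrature of `G`.
#'
#' The conditioned means carry the hazard: `h = kappa * E_t[n]` (Zeroth,
#' Model 1), `h = kappa_V * E_t[n_V]` (Model 2), `h = (a + b t) * E_t[n]`
#' (Model 3).
#'
#' @inheritParams escape_survival
#' @param t Single escape-clock time in years, >= 0.
#' @return A data.frame with columns `type`, `mean`, `var`; the total count
#'   mean/variance are in attributes `"total_mean"` and `"total_var"`.
#' @export
conditional_moments <- function(params, t) {
  stopifnot(inherits(params, "model_params"), length(t) == 1L)
  t <- check_time(t)
  P <- plist(params)
  out <- switch(model_id(params),
    zeroth = {
      m <- P$N_bar * q_zeroth(t, P$kappa)
      data.frame(type = "micrometastasis", mean = m, var = m)
    },
    model3 = {
      m <- P$N_bar * q_model3(t, P$a, P$b)
      data.frame(type = "micrometastasis", mean = m, var = m)
    },
    model2 = {
      # colouring of s-lineages into {still s, now V, escaped}; conditioned
      # on zero escapes the first two stay independent Poisson
      p_ss <- q_zeroth(t, P$kappa_s)
      p_sV <- q_two_stage(t, P$kappa_s, P$kappa_V) - p_ss
      m_s <- P$N_s_bar * p_ss
      m_V <- P$N_V_bar * q_zeroth(t, P$kappa_V) + P$N_s_bar * p_sV
      data.frame(type = c("s", "V"), mean = c(m_s, m_V), var = c(m_s, m_V))
    },
    model1 = {
      m_np <- P$N_bar * (1 - P$p_M) * exp(-(P$lam + P$kappa) * t)
      gm <- perm_lineage_moments(t, P$kappa, P$lam, P$mu)
      m_base <- P$N_bar * P$p_M
      data.frame(type = c("non_permissive", "permissive"),
                 mean = c(m_np, m_base * gm$G),
                 var  = c(m_np, m_base * (gm$H + gm$G)))
    })
  attr(out, "total_mean") <- sum(out$mean)
  attr(out, "total_var") <- sum(out$var)
  out
}

# Conditioned permissive-lineage mean factor G(t) = F_x(1, t) and second
# factorial moment H(t) = F_xx(1, t), where F(x, t) = E[x^Z 1{no escape}]
# from one permissive founder. G has a closed form through
# Int_0^t q_M ds; H = 2 mu G(t) Int_0^t G(s) ds (quadrature).
perm_lineage_moments <- function(t, kappa, lam, mu) {
  if (kappa <= 0) {
    # no killing: plain branching mean/second-moment; G = e^{(mu-lam)t}
    G <- exp((mu - lam) * t)
    Gint <- if (abs(mu - lam) < 1e-14) t else (G - 1) / (mu - lam)
    return(list(G = G, H = 2 * mu * G * Gint))
  }
  if (mu <= 1e-14) {
    return(list(G = exp(-(lam + kappa) * t), H = 0))
  }
  s <- mu + lam + kappa
  int_q <- function(tt) {
    rt <- riccati_roots(kappa, lam, mu)
    C <- (1 - rt$r1) / (1 - rt$r2)
    A <- C * exp(-rt$disc * tt)
    rt$r1 * tt + (rt$r1 - rt$r2) / rt$disc * log((1 - A) / (1 - C))
  }
  G <- function(tt) exp(2 * mu * int_q(tt) - s * tt)
  Gt <- G(t)
  Gint <- if (t == 0) 0 else
    stats::integrate(G, 0, t, rel.tol = 1e-10)$value
  list(G = Gt, H = 2 * mu * Gt * Gint)
}

#' No-escape probability for the Zeroth model under an arbitrary initial
#' count distribution
#'
#' `S(t) = E[q(t)^N]` with `q(t) = exp(-kappa t)`: the probability
#' generating function of the initial count evaluated at the per-lineage
#' no-escape probability. Used to show that the Zeroth model hazard is
#' non-increasing for any initial count distribution, not just Poisson.
#'
#' @param t Escape-clock time(s), years.
#' @param kappa Escape rate, 1/year.
#' @param count_dist A list: `list(type = "poisson", mean = )`,
#'   `list(type = "fixed", n = )`, or
#'   `list(type = "mixture", n = c(...), prob = c(...))` (point-mass
#'   mixture over counts).
#' @return Survival probabilities; hazard available via
#'   [zeroth_hazard_general()].
#' @export
zeroth_survival_general <- function(t, kappa, count_dist) {
  t <- check_time(t)
  q <- exp(-kappa * t)
  pgf <- count_pgf(count_dist)
  vapply(q, pgf, numeric(1))
}

#' @rdname zeroth_survival_general
#' @export
zeroth_hazard_general <- function(t, kappa, count_dist) {
  t <- check_time(t)
  q <- exp(-kappa * t)
  pgf <- count_pgf(count_dist)
  dpgf <- count_pgf_prime(count_dist)
  # h = -d log E[q^N]/dt = kappa q E[N q^{N-1}] / E[q^N]
  kappa * q * vapply(q, dpgf, numeric(1)) / vapply(q, pgf, numeric(1))
}

count_pgf <- function(cd) {
  switch(cd$type,
    poisson = function(x) exp(-cd$mean * (1 - x)),
    fixed   = function(x) x^cd$n,
    mixture = function(x) sum(cd$prob * x^cd$n),
    stop("unknown count distribution type '", cd$type, "'"))
}

count_pgf_prime <- function(cd) {
  switch(cd$type,
    poisson = function(x) cd$mean * exp(-cd$mean * (1 - x)),
    fixed   = function(x) if (cd$n == 0) 0 else cd$n * x^(cd$n - 1),
    mixture = function(x) sum(cd$prob * ifelse(cd$n == 0, 0,
                                               cd$n * x^pmax(cd$n - 1, 0))),
    stop("unknown count distribution type '", cd$type, "'"))
}
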