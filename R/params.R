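#' Model parameter constructors
#'
#' Four nested stochastic models describe how a patient's growth-restricted
#' micrometastases progress after resection of the primary tumour. In every
#' model the number of micrometastases present at resection is
#' Poisson-distributed, and a micrometastasis that escapes growth restriction
#' grows to clinical detectability over a fixed growth time `tau`.
#'
#' * **Zeroth model** (`zeroth_params`): each of Poisson(`N_bar`)
#'   micrometastases escapes growth restriction independently at constant
#'   rate `kappa` per year. The patient's risk is constant until an escape.
#' * **Model 1** (`model1_params`): micrometastases additionally disappear
#'   at rate `lam` per year, and those sitting in seeding-permissive
#'   micro-environments (a fraction `p_M` of initial ones) seed new
#'   growth-restricted secondaries at rate `mu` per year. Secondaries are
#'   themselves permissive (they descend from cells already proven capable
#'   of colonisation); see [simulate_patient()] for the alternative
#'   convention.
#' * **Model 2** (`model2_params`): two micrometastasis types. One-step
#'   (state V) micrometastases, Poisson(`N_V_bar`) initially, escape at rate
#'   `kappa_V`; two-step (state s) ones, Poisson(`N_s_bar`) initially, must
#'   first transition s to V at rate `kappa_s` and then escape at `kappa_V`.
#' * **Model 3** (`model3_params`): a single type whose escape rate rises
#'   linearly in time, `kappa(t) = a + b t`.
#'
#' @param N_bar,N_s_bar,N_V_bar Mean initial micrometastasis counts
#'   (dimensionless, >= 0).
#' @param kappa,kappa_s,kappa_V,lam,mu,a Rates in 1/year, >= 0.
#' @param b Escape-rate slope in 1/year^2, >= 0.
#' @param p_M Probability that an initial micrometastasis sits in a
#'   seeding-permissive environment, in [0, 1].
#' @return An object of class `model_params` with a model-specific subclass
#'   (`"zeroth_params"`, `"model1_params"`, `"model2_params"`,
#'   `"model3_params"`).
#' @examples
#' p <- zeroth_params(N_bar = 1, kappa = 0.1)
#' escape_survival(p, t = 10)
#' @name model_params
NULL

new_model_params <- function(fields, subclass, model) {
  structure(fields, class = c(subclass, "model_params"), model = model)
}

check_nonneg <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < 0) {
    stop("'", name, "' must be a single finite non-negative number, got ",
         deparse(substitute(x, parent.frame())), " = ", paste(x, collapse = ","),
         call. = FALSE)
  }
  as.numeric(x)
}

#' @rdname model_params
#' @export
zeroth_params <- function(N_bar, kappa) {
  new_model_params(
    list(N_bar = check_nonneg(N_bar, "N_bar"),
         kappa = check_nonneg(kappa, "kappa")),
    "zeroth_params", "zeroth")
}

#' @rdname model_params
#' @export
model1_params <- function(N_bar, kappa, lam, mu, p_M) {
  p_M <- check_nonneg(p_M, "p_M")
  if (p_M > 1) stop("'p_M' must lie in [0, 1]", call. = FALSE)
  new_model_params(
    list(N_bar = check_nonneg(N_bar, "N_bar"),
         kappa = check_nonneg(kappa, "kappa"),
         lam   = check_nonneg(lam, "lam"),
         mu    = check_nonneg(mu, "mu"),
         p_M   = p_M),
    "model1_params", "model1")
}

#' @rdname model_params
#' @export
model2_params <- function(N_s_bar, N_V_bar, kappa_s, kappa_V) {
  new_model_params(
    list(N_s_bar = check_nonneg(N_s_bar, "N_s_bar"),
         N_V_bar = check_nonneg(N_V_bar, "N_V_bar"),
         kappa_s = check_nonneg(kappa_s, "kappa_s"),
         kappa_V = check_nonneg(kappa_V, "kappa_V")),
    "model2_params", "model2")
}

#' @rdname model_params
#' @export
model3_params <- function(N_bar, a, b) {
  new_model_params(
    list(N_bar = check_nonneg(N_bar, "N_bar"),
         a = check_nonneg(a, "a"),
         b = check_nonneg(b, "b")),
    "model3_params", "model3")
}

#' Model identifier of a parameter object
#' @param params A `model_params` object.
#' @return One of `"zeroth"`, `"model1"`, `"model2"`, `"model3"`.
#' @export
model_id <- function(params) {
  stopifnot(inherits(params, "model_params"))
  attr(params, "model")
}

#' Names of the free parameters of a model
#' @param model Model id string.
#' @return Character vector of parameter names in canonical order.
#' @export
model_param_names <- function(model) {
  switch(match.arg(model, c("zeroth", "model1", "model2", "model3")),
         zeroth = c("N_bar", "kappa"),
         model1 = c("N_bar", "kappa", "lam", "mu", "p_M"),
         model2 = c("N_s_bar", "N_V_bar", "kappa_s", "kappa_V"),
         model3 = c("N_bar", "a", "b"))
}

#' Build a parameter object from a model id and a flat named mapping
#'
#' The inverse of `unclass()`: used when (de)serializing parameters from
#' fit results, CSV sidecars or the command line.
#'
#' @param model Model id string.
#' @param values Named list or numeric vector with the model's parameters.
#' @return A `model_params` object.
#' @export
make_params <- function(model, values) {
  values <- as.list(values)
  nm <- model_param_names(model)
  missing <- setdiff(nm, names(values))
  if (length(missing)) {
    stop("missing parameter(s) for model '", model, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(switch(model,
                 zeroth = zeroth_params, model1 = model1_params,
                 model2 = model2_params, model3 = model3_params),
          values[nm])
}

#' @export
print.model_params <- function(x, ...) {
  cat("<", model_id(x), " dormancy model parameters>\n", sep = "")
  for (nm in names(x)) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' @export
as.list.model_params <- function(x, ...) {
  c(list(model = model_id(x)), unclass(x))
}

check_time <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    stop("time 't' must be non-negative and finite (escape-clock years)",
         call. = FALSE)
  }
  as.numeric(t)
}

check_tau <- function(tau) {
  if (length(tau) != 1L || !is.numeric(tau) || !is.finite(tau) || tau <= 0) {
    stop("'tau' (growth time, years) must be a single positive number",
         call. = FALSE)
  }
  as.numeric(tau)
}
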