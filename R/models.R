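#' Construct a radiation risk model
#'
#' A risk model describes the excess cancer rate attributable to radiation in
#' an epidemiological cohort, either as excess relative risk (ERR,
#' dimensionless) or excess absolute rate (EAR, in units of 1e-4 per
#' person-year per Gy), together with the cohort baseline rate used for risk
#' transfer. The total rate decomposes as
#' \code{lambda = lambda0 * (1 + ERR) = lambda0 + EAR}, and the excess term
#' factorises into a sex-specific dose response \code{p(d, s)} times a
#' modifier \code{r(s, a, e)} in attained age \code{a} and age at exposure
#' \code{e}.
#'
#' @param id Model identifier (string).
#' @param kind `"ERR"` or `"EAR"`.
#' @param disease_class `"solid"` or `"hematopoietic"`; controls latency
#'   parameters and time-since-exposure caps.
#' @param dose_response List with `form` (one of `"linear"`,
#'   `"linear_quadratic"`, `"quadratic"`, `"power"`,
#'   `"quadratic_exponential"`, `"threshold_linear_spline"`) and, for the
#'   spline form, `knot_dose` in Gy (default 0.7).
#' @param modifiers List describing active effect modifiers: `sex` one of
#'   `"none"`, `"loglinear"` (\code{exp(sigma * s)}) or `"linear"`
#'   (\code{1 + sigma * s}); logicals `attained_age`
#'   (\code{(a / centre_age)^phi}) and `age_at_exposure`
#'   (\code{exp(psi * (e - centre_exposure_age) / 10)}); `smoking` optionally
#'   `"loglinear"` (\code{exp(theta * cpd)}). Centring constants default to
#'   70 y (attained age) and 30 y (age at exposure).
#' @param params Named numeric vector of model parameters. Recognised names:
#'   `beta` (linear dose slope per Gy or per exposure unit), `alpha`
#'   (quadratic, per Gy^2), `gamma` (power-form exponent), `beta2` (spline
#'   upper slope), `delta` (exponential-in-dose coefficient), `sigma` (sex),
#'   `phi` (attained-age power), `psi` (age-at-exposure per decade), `theta`
#'   (smoking intensity), and baseline coefficients `b0`, `b_age`, `b_sex`,
#'   `b_byr`.
#' @param covariance Symmetric positive semi-definite matrix matching
#'   `params` (row/column order = parameter order). A zero matrix means the
#'   parameters are treated as known.
#' @param aic Akaike information criterion of the fit; used for multi-model
#'   inference weights.
#' @param baseline Optional baseline specification: a list with log-linear
#'   coefficients referencing parameter names (see Details), `g_average`
#'   (pre-averaged cohort factor, default 1) and optional `screening`
#'   (list of `breaks` calendar years and `factors`). A model without a
#'   baseline must use generic risk transfer.
#' @param twin_id Optional id of a companion model linear in dose sharing the
#'   same baseline and modifiers; used by the twin rule for non-linear dose
#'   responses.
#' @param max_group Optional name of a maximum-ERR group (e.g. for smoking
#'   interaction models): within a group the pointwise maximum ERR is used.
#' @param lss_cohort Logical; if `TRUE`, cohort dosimetry and neutron
#'   weighting uncertainty factors apply.
#' @param radiation_class `"lowLET"` (doses in mSv, converted to Gy),
#'   `"radon_miner"` (cumulative WLM) or `"radon_indoor"` (Bq/m3 times
#'   exposure hours).
#'
#' @details The baseline rate is
#' \code{f(s, a, b) = exp(b0 + b_age * log(a / 70) + b_sex * s +
#' b_byr * (b - 1930) / 10)} times the averaged cohort factor `g_average` and
#' any screening factor for the calendar period; the birth year `b` is
#' derived as calendar year minus attained age.
#'
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(id, kind = c("ERR", "EAR"),
                       disease_class = c("solid", "hematopoietic"),
                       dose_response = list(form = "linear"),
                       modifiers = list(),
                       params, covariance = NULL, aic = 0,
                       baseline = NULL, twin_id = NULL, max_group = NULL,
                       lss_cohort = FALSE,
                       radiation_class = c("lowLET", "radon_miner", "radon_indoor")) {
  kind <- match.arg(kind)
  disease_class <- match.arg(disease_class)
  radiation_class <- match.arg(radiation_class)
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    abort("params must be a fully named numeric vector")
  }
  params <- unlist(params)
  forms <- c("linear", "linear_quadratic", "quadratic", "power",
             "quadratic_exponential", "threshold_linear_spline")
  if (!dose_response$form %in% forms) {
    abort(paste0("unknown dose-response form: ", dose_response$form))
  }
  if (identical(dose_response$form, "threshold_linear_spline") &&
      is.null(dose_response$knot_dose)) {
    dose_response$knot_dose <- 0.7
  }
  mod_defaults <- list(sex = "none", attained_age = FALSE,
                       age_at_exposure = FALSE, smoking = "none",
                       centre_age = 70, centre_exposure_age = 30)
  modifiers <- modifyList(mod_defaults, modifiers)
  if (is.null(covariance)) {
    covariance <- matrix(0, length(params), length(params),
                         dimnames = list(names(params), names(params)))
  }
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(dim(covariance), rep(length(params), 2L)))) {
    abort("covariance dimension must match the number of parameters")
  }
  covariance <- check_covariance(covariance)
  if (!is.null(baseline)) {
    baseline$g_average <- baseline$g_average %||% 1
    if (baseline$g_average <= 0) abort("g_average must be strictly positive")
    if (!is.null(baseline$screening) &&
        any(baseline$screening$factors <= 0)) {
      abort("screening factors must be strictly positive")
    }
  }
  structure(list(id = id, kind = kind, disease_class = disease_class,
                 dose_response = dose_response, modifiers = modifiers,
                 params = params, covariance = covariance, aic = aic,
                 baseline = baseline, twin_id = twin_id,
                 max_group = max_group, lss_cohort = lss_cohort,
                 radiation_class = radiation_class),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model %s> %s %s, dose response: %s\n", x$id, x$disease_class,
              x$kind, x$dose_response$form))
  cat("  params:", paste(sprintf("%s=%.4g", names(x$params), x$params),
                         collapse = ", "), "\n")
  if (!is.null(x$twin_id)) cat("  twin:", x$twin_id, "\n")
  invisible(x)
}

# Symmetrise and validate positive semi-definiteness; clip tiny negative
# eigenvalues (round-trip noise) but reject genuinely indefinite matrices.
check_covariance <- function(v) {
  if (max(abs(v - t(v))) > 1e-8 * max(1, max(abs(v)))) {
    abort("covariance matrix is not symmetric")
  }
  v <- (v + t(v)) / 2
  ev <- eigen(v, symmetric = TRUE)
  tol <- 1e-10 * max(sum(diag(v)), .Machine$double.eps)
  if (min(ev$values) < -tol) {
    abort("covariance matrix is not positive semi-definite")
  }
  if (min(ev$values) < 0) {
    ev$values <- pmax(ev$values, 0)
    v <- ev$vectors %*% diag(ev$values, nrow = length(ev$values)) %*% t(ev$vectors)
    dimnames(v) <- dimnames(v) %||% NULL
  }
  v
}

par_or_zero <- function(params, name) {
  if (name %in% names(params)) unname(params[[name]]) else 0
}

#' Sex-specific dose-response term p(d, s)
#'
#' Evaluates the dose response of a risk model; every supported form
#' vanishes at zero dose. Doses are in Gy for low-LET models (or in the
#' model's native exposure unit for radon models).
#'
#' @param model A [risk_model()].
#' @param d Dose (Gy), vectorised, non-negative.
#' @param params Optional parameter vector overriding the fitted one (e.g. a
#'   Monte Carlo draw).
#' @return Numeric vector of the same length as `d`.
#' @export
dose_term <- function(model, d, params = model$params) {
  if (any(d < 0)) abort("dose must be non-negative")
  beta <- par_or_zero(params, "beta")
  alpha <- par_or_zero(params, "alpha")
  switch(model$dose_response$form,
    linear = beta * d,
    quadratic = alpha * d^2,
    linear_quadratic = beta * d + alpha * d^2,
    power = {
      gamma <- par_or_zero(params, "gamma")
      if (gamma <= 0) abort("power-form exponent must be positive")
      beta * d^gamma
    },
    quadratic_exponential = {
      delta <- par_or_zero(params, "delta")
      (beta * d + alpha * d^2) * exp(delta * d)
    },
    threshold_linear_spline = {
      k <- model$dose_response$knot_dose
      beta2 <- par_or_zero(params, "beta2")
      ifelse(d <= k, beta * d, beta * k + beta2 * (d - k))
    },
    abort(paste0("unknown dose-response form: ", model$dose_response$form)))
}

#' Effect-modifier term r(s, a, e)
#'
#' Multiplicative risk modifier in sex, attained age (power law centred at
#' 70 y) and age at exposure (log-linear per decade, centred at 30 y). With
#' no active modifiers the term is exactly 1.
#'
#' @param model A [risk_model()].
#' @param s Sex indicator (-1 male, +1 female) or `"male"`/`"female"`.
#' @param a Attained age (years).
#' @param e Age at exposure (years); must not exceed `a`.
#' @param params Optional parameter vector override.
#' @param cpd Cigarettes per day (only used when a smoking modifier is
#'   configured); default 0.
#' @return Positive numeric vector.
#' @export
modifier_term <- function(model, s, a, e, params = model$params, cpd = 0) {
  if (any(a < e)) abort("attained age must be >= age at exposure")
  if (any(e < 0)) abort("age at exposure must be non-negative")
  s <- sex_indicator(s)
  m <- model$modifiers
  r <- rep(1, max(length(s), length(a), length(e)))
  if (m$sex == "loglinear") r <- r * exp(par_or_zero(params, "sigma") * s)
  if (m$sex == "linear") r <- r * (1 + par_or_zero(params, "sigma") * s)
  if (isTRUE(m$attained_age)) {
    r <- r * (a / m$centre_age)^par_or_zero(params, "phi")
  }
  if (isTRUE(m$age_at_exposure)) {
    r <- r * exp(par_or_zero(params, "psi") * (e - m$centre_exposure_age) / 10)
  }
  if (m$smoking == "loglinear") r <- r * exp(par_or_zero(params, "theta") * cpd)
  if (any(r <= 0)) abort("modifier term must be strictly positive")
  r
}

#' Excess risk term (ERR or EAR)
#'
#' Product of the dose response and the effect modifiers. For ERR-type
#' models the result is dimensionless; for EAR-type models it is in the
#' model's native unit of 1e-4 per person-year (convert with
#' [ear_to_rate()]).
#'
#' @inheritParams modifier_term
#' @param d Dose in Gy (or native exposure unit).
#' @return Numeric vector.
#' @export
excess <- function(model, d, s, a, e, params = model$params, cpd = 0) {
  dose_term(model, d, params) * modifier_term(model, s, a, e, params, cpd)
}

#' Convert a native EAR value to a rate in PY^-1
#'
#' EAR-type model coefficients follow the cohort-table convention of excess
#' cases per 1e4 person-years per Gy.
#' @param ear Numeric EAR in 1e-4 PY^-1.
#' @return Rate in PY^-1.
#' @export
ear_to_rate <- function(ear) ear * 1e-4

#' Model baseline rate
#'
#' Cohort-model baseline incidence rate
#' \code{lambda0m = f(s, a, b) * g_average * screening(year)}, in PY^-1.
#' The birth year is derived as `calendar_year - a`. Models without a
#' baseline specification (generic-transfer models) signal an error.
#'
#' @inheritParams modifier_term
#' @param calendar_year Calendar year at which the baseline is evaluated
#'   (in the cohort's own timeframe; see [lss_calendar_year()]).
#' @return Positive rate in PY^-1.
#' @export
model_baseline <- function(model, s, a, calendar_year, params = model$params) {
  b <- model$baseline
  if (is.null(b)) {
    abort(paste0("model ", model$id, " has no baseline: generic transfer required"),
          class = "radshare_generic_transfer")
  }
  s <- sex_indicator(s)
  byr <- calendar_year - a
  f <- exp(par_or_zero(params, "b0") +
             par_or_zero(params, "b_age") * log(a / 70) +
             par_or_zero(params, "b_sex") * s +
             par_or_zero(params, "b_byr") * (byr - 1930) / 10)
  scr <- 1
  if (!is.null(b$screening)) {
    idx <- findInterval(calendar_year, b$screening$breaks) + 1L
    scr <- b$screening$factors[idx]
  }
  out <- f * b$g_average * scr
  if (any(out <= 0) || any(!is.finite(out))) abort("baseline rate must be positive and finite")
  out
}

#' Draw model parameters from the fitted covariance
#'
#' One multivariate-normal draw centred at the fitted parameter vector, as
#' used per Monte Carlo iteration to propagate statistical parameter
#' uncertainty. A zero covariance returns the fitted parameters exactly.
#'
#' @param model A [risk_model()].
#' @param n Number of draws (default 1).
#' @return For `n = 1` a named vector; otherwise an `n` x p matrix.
#' @export
sample_params <- function(model, n = 1) {
  if (all(model$covariance == 0)) {
    if (n == 1) return(model$params)
    return(matrix(model$params, n, length(model$params), byrow = TRUE,
                  dimnames = list(NULL, names(model$params))))
  }
  draw <- MASS::mvrnorm(n, mu = model$params, Sigma = model$covariance)
  if (n == 1) setNames(as.numeric(draw), names(model$params)) else draw
}
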