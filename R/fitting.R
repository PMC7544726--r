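#' Specify a model form for cohort fitting
#'
#' Describes the rate model fitted to a grouped person-year table: a
#' log-linear baseline in transforms of sex and attained age, an optional
#' cohort factor over city and in-city strata, and an ERR- or EAR-type
#' excess with a chosen dose-response form and effect modifiers.
#'
#' @param kind `"ERR"` or `"EAR"`.
#' @param dose_form One of `"linear"`, `"quadratic"`, `"linear_quadratic"`,
#'   `"power"`, or `"none"` for a baseline-only model (e.g. on zero-dose
#'   strata, where a dose coefficient would be unidentifiable).
#' @param baseline_terms Subset of `c("log_age", "sex")`; the intercept `b0`
#'   is always present.
#' @param excess_modifiers Subset of `c("sex", "attained_age",
#'   "age_at_exposure")`.
#' @param cohort_terms Subset of `c("city", "in_city")` entering the
#'   log-linear cohort factor g.
#' @param disease_class `"solid"` or `"hematopoietic"`.
#' @return List of class `fit_spec`.
#' @export
fit_spec <- function(kind = c("ERR", "EAR"),
                     dose_form = c("linear", "quadratic", "linear_quadratic",
                                   "power", "none"),
                     baseline_terms = c("log_age", "sex"),
                     excess_modifiers = character(),
                     cohort_terms = character(),
                     disease_class = c("solid", "hematopoietic")) {
  kind <- match.arg(kind)
  dose_form <- match.arg(dose_form)
  disease_class <- match.arg(disease_class)
  stopifnot(all(baseline_terms %in% c("log_age", "sex")),
            all(excess_modifiers %in% c("sex", "attained_age", "age_at_exposure")),
            all(cohort_terms %in% c("city", "in_city")))
  structure(list(kind = kind, dose_form = dose_form,
                 baseline_terms = baseline_terms,
                 excess_modifiers = excess_modifiers,
                 cohort_terms = cohort_terms,
                 disease_class = disease_class),
            class = "fit_spec")
}

fit_param_names <- function(spec) {
  c("b0",
    if ("log_age" %in% spec$baseline_terms) "b_age",
    if ("sex" %in% spec$baseline_terms) "b_sex",
    if ("city" %in% spec$cohort_terms) "g_city",
    if ("in_city" %in% spec$cohort_terms) "g_ic",
    switch(spec$dose_form,
           linear = "beta", quadratic = "alpha",
           linear_quadratic = c("beta", "alpha"), power = c("beta", "gamma"),
           none = character(0)),
    if ("sex" %in% spec$excess_modifiers) "sigma",
    if ("attained_age" %in% spec$excess_modifiers) "phi",
    if ("age_at_exposure" %in% spec$excess_modifiers) "psi")
}

dose_param_names <- function(spec) {
  switch(spec$dose_form, linear = "beta", quadratic = "alpha",
         linear_quadratic = c("beta", "alpha"), power = c("beta", "gamma"),
         none = character(0))
}

#' Validate a grouped cohort person-year table
#'
#' Columns: sex indicator `s` (-1/+1), attained age `a` and age at exposure
#' `e` (midpoints, years), dose `d` (Gy), city `c` (-1/+1), in-city `ic`
#' (0/1), observed cases `n` (non-negative integers) and person-years `py`
#' (positive).
#'
#' @param df Data frame with the columns above (`c` and `ic` optional,
#'   defaulting to 0).
#' @return Validated tibble of class `cohort_cells`.
#' @export
cohort_cells <- function(df) {
  df <- as_tibble(df)
  if (!"c" %in% names(df)) df$c <- 0
  if (!"ic" %in% names(df)) df$ic <- 0
  req <- c("s", "a", "e", "d", "c", "ic", "n", "py")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("cohort cells missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(df$py <= 0)) abort("person-years must be positive")
  if (any(df$n < 0) || any(df$n != round(df$n))) {
    abort("case counts must be non-negative integers")
  }
  if (!all(df$s %in% c(-1, 1))) abort("sex indicator must be -1/+1")
  if (!all(df$ic %in% c(0, 1))) abort("in-city indicator must be 0/1")
  if (any(df$d < 0)) abort("doses must be non-negative")
  if (any(df$a < df$e)) abort("attained age must be >= age at exposure")
  class(df) <- c("cohort_cells", class(df))
  df[req]
}

cell_rate <- function(spec, params, cells) {
  p <- function(nm) if (nm %in% names(params)) params[[nm]] else 0
  f <- exp(p("b0") +
             (if ("log_age" %in% spec$baseline_terms) p("b_age") * log(cells$a / 70) else 0) +
             (if ("sex" %in% spec$baseline_terms) p("b_sex") * cells$s else 0))
  g <- exp((if ("city" %in% spec$cohort_terms) p("g_city") * cells$c else 0) +
             (if ("in_city" %in% spec$cohort_terms) p("g_ic") * cells$ic else 0))
  pd <- switch(spec$dose_form,
    none = rep(0, nrow(cells)),
    linear = p("beta") * cells$d,
    quadratic = p("alpha") * cells$d^2,
    linear_quadratic = p("beta") * cells$d + p("alpha") * cells$d^2,
    power = {
      if (p("gamma") <= 0) return(rep(NA_real_, nrow(cells)))
      p("beta") * cells$d^p("gamma")
    })
  r <- rep(1, nrow(cells))
  if ("sex" %in% spec$excess_modifiers) r <- r * exp(p("sigma") * cells$s)
  if ("attained_age" %in% spec$excess_modifiers) r <- r * (cells$a / 70)^p("phi")
  if ("age_at_exposure" %in% spec$excess_modifiers) {
    r <- r * exp(p("psi") * (cells$e - 30) / 10)
  }
  if (spec$kind == "ERR") f * g * (1 + pd * r) else f * g + 1e-4 * pd * r
}

#' Expected case counts per cohort cell
#'
#' `mu_i = lambda(params, X_i) * PY_i`.
#'
#' @param spec A [fit_spec()].
#' @param params Named parameter vector.
#' @param cells A [cohort_cells()] table.
#' @return Numeric vector of expected counts.
#' @export
expected_counts <- function(spec, params, cells) {
  cell_rate(spec, params, cells) * cells$py
}

#' Poisson deviance of a grouped person-year table
#'
#' `dev = 2 sum_{n_i > 0} [n_i log(n_i / mu_i) - (n_i - mu_i)]
#'        + 2 sum_{n_i = 0} mu_i`; non-negative, and zero iff the expected
#' counts match the observed counts in every non-empty cell.
#'
#' @param n Observed counts.
#' @param mu Expected counts, positive.
#' @return Deviance.
#' @export
poisson_deviance <- function(n, mu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) return(Inf)
  pos <- n > 0
  2 * sum(n[pos] * log(n[pos] / mu[pos]) - (n[pos] - mu[pos])) +
    2 * sum(mu[!pos])
}

#' AIC from a deviance
#'
#' `AIC = dev + 2 * n_params`.
#' @param deviance Model deviance.
#' @param n_params Number of fitted parameters.
#' @return AIC value.
#' @export
aic_from_deviance <- function(deviance, n_params) deviance + 2 * n_params

default_start <- function(spec, cells) {
  start <- setNames(rep(0, length(fit_param_names(spec))), fit_param_names(spec))
  start[["b0"]] <- log(max(sum(cells$n), 0.5) / sum(cells$py))
  if ("gamma" %in% names(start)) start[["gamma"]] <- 1
  start
}

#' Fit a rate model to cohort cells by deviance minimisation
#'
#' Quasi-Newton (BFGS) minimisation of the Poisson deviance with numerically
#' differenced gradients; by default three starts (the analytic intercept
#' start plus jittered copies) guard against local minima. The covariance is
#' the inverse of half the deviance Hessian at the optimum (observed
#' information); Wald p-values are reported per parameter.
#'
#' @param spec A [fit_spec()].
#' @param cells A [cohort_cells()] table.
#' @param start Optional named start vector.
#' @param n_starts Number of starts (>= 1).
#' @return Object of class `cohort_fit` with elements `params`,
#'   `covariance`, `deviance`, `aic`, `p_values`, `converged`, `spec`.
#' @export
fit_cohort <- function(spec, cells, start = NULL, n_starts = 3) {
  cells <- cohort_cells(cells)
  nm <- fit_param_names(spec)
  if (is.null(start)) start <- default_start(spec, cells)
  if (!all(nm %in% names(start))) abort("start vector is missing parameters")
  start <- start[nm]
  obj <- function(par) {
    poisson_deviance(cells$n, expected_counts(spec, setNames(par, nm), cells))
  }
  starts <- list(start)
  if (n_starts > 1) {
    for (j in seq_len(n_starts - 1)) {
      starts[[j + 1]] <- start + rnorm(length(start), sd = 0.1)
    }
  }
  best <- NULL
  for (s0 in starts) {
    res <- tryCatch(
      optim(s0, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) abort("deviance minimisation failed from every start")
  # polish + Hessian at the optimum
  res <- optim(best$par, obj, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  if (res$value > best$value + 1e-6) res <- best
  params <- setNames(res$par, nm)
  H <- if (!is.null(res$hessian)) res$hessian else
    optim(res$par, obj, method = "BFGS", hessian = TRUE,
          control = list(maxit = 1))$hessian
  cov <- tryCatch(2 * solve(H), error = function(e) NULL)
  singular <- is.null(cov)
  if (singular) {
    cov <- matrix(NA_real_, length(nm), length(nm))
  } else {
    cov <- tryCatch(check_covariance(cov), error = function(e) {
      # indefinite observed information away from a clean optimum: flag it
      singular <<- TRUE
      matrix(NA_real_, length(nm), length(nm))
    })
  }
  dimnames(cov) <- list(nm, nm)
  se <- sqrt(pmax(diag(cov), 0))
  pvals <- 2 * pnorm(-abs(params) / se)
  structure(list(spec = spec, params = params, covariance = cov,
                 deviance = res$value,
                 aic = aic_from_deviance(res$value, length(nm)),
                 p_values = pvals, se = se,
                 converged = (res$convergence %||% 0) == 0 && !singular,
                 n_cells = nrow(cells)),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("<cohort_fit %s/%s> deviance %.3f, AIC %.3f over %d cells\n",
              x$spec$kind, x$spec$dose_form, x$deviance, x$aic, x$n_cells))
  print(tidy.cohort_fit(x))
  invisible(x)
}

#' Tidy a cohort fit
#' @param x A `cohort_fit`.
#' @param ... Unused.
#' @return Tibble with term, estimate, std.error, p.value.
#' @export
tidy.cohort_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params),
         std.error = unname(x$se), p.value = unname(x$p_values))
}

#' One-row cohort fit summary
#' @param x A `cohort_fit`.
#' @param ... Unused.
#' @return Tibble with deviance, AIC, parameter count, convergence flag.
#' @export
glance.cohort_fit <- function(x, ...) {
  tibble(deviance = x$deviance, aic = x$aic, n_params = length(x$params),
         n_cells = x$n_cells, converged = x$converged)
}

#' Likelihood-ratio test between nested cohort fits
#'
#' @param nested,full `cohort_fit` objects, the nested model a restriction
#'   of the full one.
#' @return p-value from the chi-square distribution with degrees of freedom
#'   equal to the parameter-count difference.
#' @export
likelihood_ratio_test <- function(nested, full) {
  df <- length(full$params) - length(nested$params)
  if (df < 0) abort("the nested model must have fewer parameters")
  ddev <- max(nested$deviance - full$deviance, 0)
  if (df == 0) return(if (ddev <= 1e-8) 1 else NA_real_)
  pchisq(ddev, df = df, lower.tail = FALSE)
}

#' Prune non-significant effect modifiers from a model specification
#'
#' Iteratively refits the model dropping the least significant removable
#' term (likelihood-ratio test at level `alpha`) until all remaining terms
#' are significant. The primary dose-response coefficients are never
#' removed, even when their confidence interval includes zero.
#'
#' @param spec A [fit_spec()].
#' @param cells A [cohort_cells()] table.
#' @param alpha Significance level (default 0.05).
#' @param n_starts Starts per fit.
#' @return List with the pruned `spec` and its `fit`.
#' @export
prune_fit <- function(spec, cells, alpha = 0.05, n_starts = 3) {
  fit <- fit_cohort(spec, cells, n_starts = n_starts)
  repeat {
    candidates <- character(0)
    if (length(spec$excess_modifiers)) {
      candidates <- c(candidates, paste("mod", spec$excess_modifiers, sep = ":"))
    }
    if (length(spec$baseline_terms)) {
      candidates <- c(candidates, paste("base", spec$baseline_terms, sep = ":"))
    }
    if (!length(candidates)) break
    pvals <- map_dbl(candidates, function(key) {
      sp <- drop_term(spec, key)
      nested <- tryCatch(fit_cohort(sp, cells, n_starts = n_starts),
                         error = function(e) NULL)
      if (is.null(nested)) return(0)  # cannot drop
      likelihood_ratio_test(nested, fit)
    })
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha) break
    spec <- drop_term(spec, candidates[worst])
    fit <- fit_cohort(spec, cells, n_starts = n_starts)
  }
  list(spec = spec, fit = fit)
}

drop_term <- function(spec, key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  if (parts[1] == "mod") {
    spec$excess_modifiers <- setdiff(spec$excess_modifiers, parts[2])
  } else {
    spec$baseline_terms <- setdiff(spec$baseline_terms, parts[2])
  }
  spec
}

#' Average the cohort factor over city/in-city strata
#'
#' The fitted cohort factor g(c, IC) is meaningless for target populations,
#' so it is averaged over the cohort strata using cases or person-years as
#' weights; the average becomes the `g_average` multiplier of the
#' cohort-independent baseline.
#'
#' @param fit A `cohort_fit`.
#' @param cells The fitted [cohort_cells()].
#' @param weight `"cases"` or `"py"`.
#' @return Scalar weighted mean of g.
#' @export
average_cohort_factor <- function(fit, cells, weight = c("cases", "py")) {
  weight <- match.arg(weight)
  p <- function(nm) if (nm %in% names(fit$params)) fit$params[[nm]] else 0
  strata <- cells |>
    mutate(g = exp(p("g_city") * .data$c + p("g_ic") * .data$ic),
           w = if (weight == "cases") .data$n else .data$py) |>
    group_by(.data$c, .data$ic) |>
    summarise(g = first(.data$g), w = sum(.data$w), .groups = "drop")
  sum(strata$g * strata$w) / sum(strata$w)
}

#' Convert a cohort fit into an engine-ready risk model
#'
#' Maps the fitted baseline, cohort-factor average, dose response and
#' modifiers into a [risk_model()] whose parameters and covariance flow
#' directly into the Monte Carlo engine.
#'
#' @param fit A `cohort_fit`.
#' @param cells The fitted cells (for the cohort-factor average).
#' @param id Model id.
#' @param weight Averaging weight for the cohort factor.
#' @param ... Passed to [risk_model()] (e.g. `twin_id`, `lss_cohort`).
#' @return A `risk_model`.
#' @export
as_risk_model <- function(fit, cells, id, weight = "cases", ...) {
  spec <- fit$spec
  if (identical(spec$dose_form, "none")) {
    abort("a baseline-only fit carries no dose response to transfer")
  }
  keep_names <- setdiff(names(fit$params), c("g_city", "g_ic"))
  params <- fit$params[keep_names]
  cov <- fit$covariance[keep_names, keep_names, drop = FALSE]
  risk_model(
    id = id, kind = spec$kind, disease_class = spec$disease_class,
    dose_response = list(form = spec$dose_form),
    modifiers = list(
      sex = if ("sex" %in% spec$excess_modifiers) "loglinear" else "none",
      attained_age = "attained_age" %in% spec$excess_modifiers,
      age_at_exposure = "age_at_exposure" %in% spec$excess_modifiers),
    params = params, covariance = cov, aic = fit$aic,
    baseline = list(g_average = average_cohort_factor(fit, cells, weight)),
    ...)
}
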