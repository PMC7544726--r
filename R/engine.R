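#' Specify a single radiation exposure event
#'
#' @param year Calendar year of the exposure.
#' @param dose Dose uncertainty distribution: a list with `dist` one of
#'   `"fixed"` (`value`), `"normal"` (`mean`, `sd`; truncated at 0 by
#'   rejection), `"lognormal"` (`gm`, `gsd`), `"uniform"` (`min`, `max`) or
#'   `"triangular"` (`min`, `mode`, `max`). Units: mSv for low-LET
#'   exposures, cumulative WLM for miner radon, average Bq/m3 for indoor
#'   radon (total exposure = concentration x `duration_hours`).
#' @param duration_hours Optional exposure duration in hours; needed to
#'   derive a dose rate for the DREF and required for indoor radon.
#' @param radiation_class `"lowLET"`, `"radon_miner"` or `"radon_indoor"`.
#' @param organ_class `"internal"` or `"external"` (neutron sensitivity).
#' @return List of class `exposure_event`.
#' @export
exposure_event <- function(year, dose, duration_hours = NULL,
                           radiation_class = c("lowLET", "radon_miner", "radon_indoor"),
                           organ_class = c("internal", "external")) {
  radiation_class <- match.arg(radiation_class)
  organ_class <- match.arg(organ_class)
  if (is.numeric(dose)) dose <- list(dist = "fixed", value = dose)
  if (radiation_class == "radon_indoor" && is.null(duration_hours)) {
    abort("indoor radon exposure requires duration_hours")
  }
  structure(list(year = year, dose = dose, duration_hours = duration_hours,
                 radiation_class = radiation_class, organ_class = organ_class),
            class = "exposure_event")
}

#' Specify a diagnosed cancer case
#'
#' @param cancer_group Cancer group code (e.g. `"DIG"`, `"HEM3"`).
#' @param sex `"male"` or `"female"`.
#' @param birth_year Calendar year of birth.
#' @param diagnosis_year Calendar year of diagnosis; attained age is
#'   `diagnosis_year - birth_year`.
#' @param exposures List of [exposure_event()]s, all between birth and
#'   diagnosis.
#' @param smoking Optional smoking history: list with `status` in
#'   `"never"`, `"current"`, `"past"`, `"unknown"`, and for (ex-)smokers
#'   `intensity` (cigarettes/day), `start_age`, `stop_age`.
#' @return List of class `case_spec`.
#' @export
case_spec <- function(cancer_group, sex, birth_year, diagnosis_year,
                      exposures, smoking = NULL) {
  sex_indicator(sex)  # validates
  if (diagnosis_year < birth_year) abort("diagnosis must not precede birth")
  years <- map_dbl(exposures, "year")
  if (any(years < birth_year) || any(years > diagnosis_year)) {
    abort("exposure years must lie between birth and diagnosis")
  }
  structure(list(cancer_group = cancer_group, sex = sex,
                 birth_year = birth_year, diagnosis_year = diagnosis_year,
                 exposures = exposures, smoking = smoking),
            class = "case_spec")
}

#' Bundle risk models with their multi-model-inference weights
#'
#' @param id Identifier of the set.
#' @param cancer_group Cancer group the set applies to.
#' @param models List of [risk_model()]s (named by their ids or not).
#' @param tree Optional [weight_tree()]; defaults to a single branch with
#'   AIC weights over all non-twin models.
#' @return Object of class `model_set`.
#' @export
model_set <- function(id, cancer_group, models, tree = NULL) {
  names(models) <- map_chr(models, "id")
  for (m in models) {
    if (!is.null(m$twin_id) && !m$twin_id %in% names(models)) {
      abort(sprintf("twin model '%s' of '%s' is missing from the set",
                    m$twin_id, m$id))
    }
  }
  if (is.null(tree)) {
    twin_ids <- unlist(map(models, "twin_id"))
    primary <- setdiff(names(models), twin_ids)
    tree <- weight_tree(list(list(weight = 1, model_ids = primary,
                                  aics = map_dbl(models[primary], "aic"))))
  }
  if (!all(tree$leaves$model_id %in% names(models))) {
    abort("weight tree references models absent from the set")
  }
  structure(list(id = id, cancer_group = cancer_group, models = models,
                 tree = tree), class = "model_set")
}

#' Assigned share of radiation
#'
#' `Z = h / (lambda0 + h)`: the probability that the diagnosed cancer was
#' caused by the past exposure, given total excess rate `h` and baseline
#' rate `lambda0`. Negative excess (possible under Gaussian parameter
#' sampling of non-significant risks) floors Z at 0.
#'
#' @param h Excess rate (PY^-1).
#' @param lambda0 Baseline rate (PY^-1), positive.
#' @return Values in [0, 1).
#' @export
assigned_share <- function(h, lambda0) {
  if (any(lambda0 <= 0)) abort("baseline rate must be positive")
  hp <- pmax(h, 0)
  hp / (lambda0 + hp)
}

#' Cap the time since exposure to the cohort follow-up window
#'
#' The epidemiological follow-up supports solid-cancer risk up to 53 years
#' since exposure and hematopoietic risk between 5 and 56 years; outside
#' these windows the model evaluation time is clamped (the latency factor
#' always uses the raw time).
#'
#' @param disease_class `"solid"` or `"hematopoietic"`.
#' @param t Time since exposure (years), non-negative.
#' @return Effective time used for model evaluation.
#' @export
capped_time_since_exposure <- function(disease_class, t) {
  if (any(t < 0)) abort("time since exposure must be non-negative")
  if (disease_class == "solid") pmin(t, 53) else pmin(pmax(t, 5), 56)
}

#' Pointwise maximum-ERR rule
#'
#' Conservative combination of eligible models (e.g. simple and generalized
#' smoking-interaction lung models): the element-wise maximum ERR across the
#' group, per iteration.
#'
#' @param err_values Numeric vector, or list/matrix of per-model ERR vectors.
#' @return Element-wise maximum.
#' @export
max_err_rule <- function(err_values) {
  if (is.list(err_values)) err_values <- do.call(rbind, err_values)
  if (is.matrix(err_values)) return(apply(err_values, 2, max))
  max(err_values)
}

#' Twin rule for non-linear dose responses
#'
#' Within one iteration, the assigned share is computed both for the
#' selected non-linear model and its linear twin (all shared samples
#' identical), and the maximum of the two is retained. Since the non-linear
#' leukaemia dose responses have positive curvature, this forces the linear
#' twin at sufficiently low doses and stabilises fractionated-exposure
#' estimates.
#'
#' @param z_selected,z_twin Assigned-share values from the same iteration.
#' @return Pairwise maximum.
#' @export
twin_rule <- function(z_selected, z_twin) pmax(z_selected, z_twin)

#' Combine multiple exposures into one assigned share
#'
#' Mixed-transfer combination over exposures with a shared transfer weight:
#' `Z = [(1-f) sum h_m,i + f sum h_m,i B_i] /
#'      [lambda0 + (1-f) sum h_m,i + f sum h_m,i B_i]`.
#' A negative combined excess is floored at zero after summation (the
#' sampled correlation structure is preserved in the intermediate sums).
#'
#' @param h_m Per-exposure model excess rates (PY^-1).
#' @param B Per-exposure baseline ratios.
#' @param f Transfer weight in [0, 1].
#' @param lambda0 Target-population baseline rate.
#' @return A single Z in [0, 1).
#' @export
combine_exposures <- function(h_m, B, f, lambda0) {
  if (length(h_m) != length(B)) abort("h_m and B must have equal length")
  s <- (1 - f) * sum(h_m) + f * sum(h_m * B)
  assigned_share(s, lambda0)
}

# --- dose sampling ---------------------------------------------------------

sample_dose <- function(dose, n = 1) {
  switch(dose$dist,
    fixed = rep(dose$value, n),
    normal = {
      out <- rnorm(n, dose$mean, dose$sd)
      bad <- out < 0
      while (any(bad)) {  # rejection at zero
        out[bad] <- rnorm(sum(bad), dose$mean, dose$sd)
        bad <- out < 0
      }
      out
    },
    lognormal = rlnorm(n, meanlog = log(dose$gm), sdlog = log(dose$gsd)),
    uniform = runif(n, dose$min, dose$max),
    triangular = rtriangular(n, dose$min, dose$mode, dose$max),
    abort(paste0("unknown dose distribution: ", dose$dist)))
}

dose_point_value <- function(dose) {
  switch(dose$dist,
    fixed = dose$value,
    normal = dose$mean,
    lognormal = dose$gm,
    uniform = (dose$min + dose$max) / 2,
    triangular = (dose$min + dose$mode + dose$max) / 3,
    abort(paste0("unknown dose distribution: ", dose$dist)))
}

# --- run configuration -----------------------------------------------------

#' Engine run configuration
#'
#' @param iterations Number of Monte Carlo iterations (default 5000,
#'   maximum 50,000).
#' @param percentiles Percentiles (in percent) reported in the summary.
#' @param transfer `"uniform"` (f ~ U(0,1)) or `"fixed"` (f = `fixed_f`).
#' @param fixed_f Transfer weight used in fixed mode.
#' @param sample_params,sample_latency,sample_dose,sample_baseline,
#'   cohort_factors,dref Logical switches for the individual uncertainty
#'   sources; turning one off uses its central value.
#' @param mmi_mode `"stratified"` or `"random"` model assignment.
#' @param neutron_sensitivity Named vector of neutron-weight sensitivities
#'   per organ class (default no effect).
#' @param smoking_prevalence Optional prevalence tibble (see
#'   [generate_smoking_prevalence()]) used when smoking status is unknown.
#' @return List of class `run_config`.
#' @export
run_config <- function(iterations = 5000, percentiles = c(2.5, 16, 50, 84, 97.5),
                       transfer = c("uniform", "fixed"), fixed_f = 0.5,
                       sample_params = TRUE, sample_latency = TRUE,
                       sample_dose = TRUE, sample_baseline = TRUE,
                       cohort_factors = TRUE, dref = TRUE,
                       sample_generic_b = TRUE,
                       mmi_mode = c("stratified", "random"),
                       neutron_sensitivity = c(internal = 0, external = 0),
                       smoking_prevalence = NULL) {
  transfer <- match.arg(transfer)
  mmi_mode <- match.arg(mmi_mode)
  if (iterations < 1 || iterations > 50000) {
    abort("iterations must lie between 1 and 50,000")
  }
  structure(list(iterations = as.integer(iterations), percentiles = percentiles,
                 transfer = transfer, fixed_f = fixed_f,
                 sample_params = sample_params, sample_latency = sample_latency,
                 sample_dose = sample_dose, sample_baseline = sample_baseline,
                 cohort_factors = cohort_factors, dref = dref,
                 sample_generic_b = sample_generic_b,
                 mmi_mode = mmi_mode, neutron_sensitivity = neutron_sensitivity,
                 smoking_prevalence = smoking_prevalence),
            class = "run_config")
}

#' Configuration with every uncertainty source frozen
#'
#' Point parameters, fixed f = 0.5 (or as given), no DREF, central doses,
#' point baseline rates, central latency parameters: the resulting Z sample
#' is degenerate and equals the closed-form mixed-transfer value.
#'
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
frozen_config <- function(...) {
  run_config(transfer = "fixed", sample_params = FALSE, sample_latency = FALSE,
             sample_dose = FALSE, sample_baseline = FALSE,
             cohort_factors = FALSE, dref = FALSE, sample_generic_b = FALSE, ...)
}

central_latency <- function(disease_class) {
  if (disease_class == "solid") list(t0 = 3.5, eta = 6.25)
  else list(t0 = 1.5, eta = 7.66)
}

# --- per-iteration excess --------------------------------------------------

# Adjusted per-exposure excess term (ERR or EAR in native units) for one
# model under a shared iteration context. Returns a vector over exposures.
adjusted_excess_terms <- function(model, params, case, ctx) {
  s <- sex_indicator(case$sex)
  n_exp <- length(case$exposures)
  out <- numeric(n_exp)
  for (i in seq_len(n_exp)) {
    ex <- case$exposures[[i]]
    e_i <- ex$year - case$birth_year
    t_raw <- case$diagnosis_year - ex$year
    t_eff <- capped_time_since_exposure(model$disease_class, t_raw)
    a_eff <- e_i + t_eff
    d <- ctx$doses[[i]]
    if (ex$radiation_class == "lowLET") d_model <- d / 1000  # mSv -> Gy
    else if (ex$radiation_class == "radon_indoor") d_model <- d * ex$duration_hours
    else d_model <- d
    x <- excess(model, d_model, s, a_eff, e_i, params, cpd = ctx$cpd)
    x <- x * latency_factor(t_raw, ctx$latency$t0, ctx$latency$eta)
    if (ex$radiation_class == "lowLET" && !is.null(ctx$dref_u)) {
      dr <- if (is.null(ex$duration_hours)) NA_real_ else d / ex$duration_hours
      x <- x / dref_value(ctx$dref_u, dref_gsd(dr))
    }
    if (isTRUE(model$lss_cohort) && !is.null(ctx$cohort)) {
      x <- x / ctx$cohort$dosimetry_factor * ctx$cohort$neutron_factor
    }
    out[i] <- x
  }
  out
}

#' Per-exposure model excess rate for one iteration
#'
#' Evaluates the model excess at the capped evaluation ages, applies the
#' latency factor at the raw time since exposure, the DREF for low-LET
#' exposures with known dose rate, and the cohort dosimetry/neutron factors
#' for cohort-fitted models. For ERR models the absolute model excess rate
#' is `lambda0m * ERR`.
#'
#' @param model A [risk_model()] with a baseline specification.
#' @param params Sampled (or fitted) parameter vector.
#' @param case A [case_spec()].
#' @param ctx Iteration context: list with `doses` (sampled, native input
#'   units), `latency` (`t0`, `eta`), optional `dref_u` percentile,
#'   optional `cohort` factors, `cpd` smoking intensity.
#' @return Tibble with per-exposure `h_m` (PY^-1) and `lambda0m`.
#' @export
exposure_excess <- function(model, params, case, ctx) {
  x <- adjusted_excess_terms(model, params, case, ctx)
  a <- case$diagnosis_year - case$birth_year
  lss_years <- map_dbl(case$exposures, function(ex) {
    t_eff <- capped_time_since_exposure(model$disease_class,
                                        case$diagnosis_year - ex$year)
    1945 + t_eff
  })
  if (!is.null(model$baseline)) {
    lam0m <- map_dbl(lss_years, function(y) {
      model_baseline(model, case$sex, a, y, params)
    })
    h_m <- if (model$kind == "ERR") lam0m * x else ear_to_rate(x)
  } else {
    lam0m <- rep(NA_real_, length(x))
    h_m <- rep(NA_real_, length(x))  # resolved against the target baseline
  }
  tibble(exposure = seq_along(x), term = x, h_m = h_m, lambda0m = lam0m)
}

# Z for one model in one iteration (shared ctx; params sampled per model).
iteration_z <- function(model, case, set, ctx, cfg) {
  params <- if (cfg$sample_params) sample_params(model) else model$params
  if (!is.null(model$max_group)) {
    group <- keep(set$models, function(m) identical(m$max_group, model$max_group))
    terms <- map(group, function(m) {
      p <- if (cfg$sample_params && !identical(m$id, model$id)) sample_params(m) else
        if (identical(m$id, model$id)) params else m$params
      adjusted_excess_terms(m, p, case, ctx)
    })
    x <- max_err_rule(terms)
    ex_tbl <- tibble(term = x)
    has_baseline <- !is.null(model$baseline)
    if (has_baseline) {
      a <- case$diagnosis_year - case$birth_year
      lam0m <- map_dbl(case$exposures, function(ex) {
        t_eff <- capped_time_since_exposure(model$disease_class,
                                            case$diagnosis_year - ex$year)
        model_baseline(model, case$sex, a, 1945 + t_eff, params)
      })
      ex_tbl$lambda0m <- lam0m
      ex_tbl$h_m <- if (model$kind == "ERR") lam0m * x else ear_to_rate(x)
    } else {
      ex_tbl$lambda0m <- NA_real_
      ex_tbl$h_m <- NA_real_
    }
  } else {
    ex_tbl <- exposure_excess(model, params, case, ctx)
  }
  if (!is.null(model$baseline)) {
    B <- ctx$lambda0 / ex_tbl$lambda0m
    h_m <- ex_tbl$h_m
  } else {
    # Generic transfer: B sampled log-uniformly; the implied model baseline
    # is lambda0 / B, so ERR models get h_m = lambda0 * ERR / B.
    B <- rep(ctx$generic_B, nrow(ex_tbl))
    h_m <- if (model$kind == "ERR") ctx$lambda0 * ex_tbl$term / B
           else ear_to_rate(ex_tbl$term)
  }
  combine_exposures(h_m, B, ctx$f, ctx$lambda0)
}

sample_smoking <- function(case, cfg) {
  sm <- case$smoking
  if (is.null(sm) || identical(sm$status, "never")) return(0)
  if (sm$status %in% c("current", "past")) return(sm$intensity %||% 0)
  prev <- cfg$smoking_prevalence
  if (is.null(prev)) return(0)
  prev <- prev[tolower(prev$sex) == tolower(case$sex), ]
  st <- sample(prev$status, 1, prob = prev$prob)
  row <- prev[prev$status == st, ]
  if (st == "never") 0 else max(0, rnorm(1, row$cpd_mean, row$cpd_sd))
}

#' Run the full Monte Carlo assigned-share computation for one case
#'
#' Executes the per-iteration protocol: assign a risk model in proportion to
#' the multi-model-inference weights; sample its parameters from the fitted
#' covariance; sample the latency parameters, the transfer weight f, the
#' DREF percentile, the target-population baseline (Poisson), the cohort
#' dosimetry/neutron factors and the per-exposure doses; evaluate the
#' mixed-transfer multiple-exposure assigned share; apply the twin rule for
#' non-linear models. Deterministic under a fixed seed.
#'
#' @param case A [case_spec()].
#' @param set A [model_set()] for the case's cancer group.
#' @param population A [population_table()].
#' @param config A [run_config()].
#' @param seed Optional integer seed.
#' @return A [z_distribution] object.
#' @export
run_case <- function(case, set, population, config = run_config(), seed = NULL) {
  if (!inherits(config, "run_config")) abort("config must be a run_config()")
  if (!is.null(set$cancer_group) && !is.null(case$cancer_group) &&
      !identical(case$cancer_group, set$cancer_group)) {
    abort(sprintf("case cancer group '%s' does not match model set '%s'",
                  case$cancer_group, set$cancer_group))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- config$iterations
  a <- case$diagnosis_year - case$birth_year
  model_ids <- assign_models(set$tree, n, config$mmi_mode)
  pop_row <- pop_lookup(population, case$sex, a, case$diagnosis_year)
  lambda0_point <- pop_row$rate
  lambda0_draws <- if (config$sample_baseline) {
    pmax(rpois(n, max(pop_row$cases, 0.5)), 0.5) / pop_row$person_years
  } else rep(lambda0_point, n)
  any_lss <- any(map_lgl(set$models, "lss_cohort"))
  z <- numeric(n)
  sel <- character(n)
  for (k in seq_len(n)) {
    model <- set$models[[model_ids[k]]]
    ctx <- list(
      latency = if (config$sample_latency) sample_latency(model$disease_class)
                else central_latency(model$disease_class),
      f = if (config$transfer == "uniform") runif(1) else config$fixed_f,
      dref_u = if (config$dref) runif(1) else NULL,
      lambda0 = lambda0_draws[k],
      generic_B = if (is.null(model$baseline) && config$sample_generic_b)
                    generic_baseline_ratio(1) else 1,
      doses = map(case$exposures, function(ex) {
        if (config$sample_dose) sample_dose(ex$dose) else dose_point_value(ex$dose)
      }),
      cohort = if (any_lss && config$cohort_factors)
                 sample_cohort_factors(case$exposures[[1]]$organ_class,
                                       config$neutron_sensitivity) else NULL,
      cpd = sample_smoking(case, config)
    )
    z_k <- iteration_z(model, case, set, ctx, config)
    if (!is.null(model$twin_id)) {
      z_twin <- iteration_z(set$models[[model$twin_id]], case, set, ctx, config)
      z_k <- twin_rule(z_k, z_twin)
    }
    z[k] <- z_k
    sel[k] <- model$id
  }
  z_distribution(z, models = sel,
                 percentiles = config$percentiles,
                 meta = list(seed = seed, iterations = n, model_set = set$id))
}
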