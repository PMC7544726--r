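# Shared fixtures, all built in code.

# Small deterministic population table.
make_pop <- function(seed = 100) {
  withr::with_seed(seed, generate_population_table(
    years = 2000:2010, age_max = 90, py_scale = 1e6))
}

# Bare linear ERR model: constant slope, attained-age power, known baseline.
make_err_model <- function(id = "ERR-TEST", beta = 0.5, phi = NULL,
                           b0 = log(2e-4), b_age = 3, cov = NULL,
                           g_average = 1, ...) {
  params <- c(beta = beta, b0 = b0, b_age = b_age)
  modifiers <- list()
  if (!is.null(phi)) {
    params <- c(params, phi = phi)
    modifiers$attained_age <- TRUE
  }
  risk_model(id = id, kind = "ERR", disease_class = "solid",
             dose_response = list(form = "linear"), modifiers = modifiers,
             params = params, covariance = cov, aic = 0,
             baseline = list(g_average = g_average), ...)
}

make_quadratic_model <- function(id = "QUAD", alpha = 1, twin_id = NULL,
                                 disease_class = "hematopoietic") {
  risk_model(id = id, kind = "ERR", disease_class = disease_class,
             dose_response = list(form = "quadratic"),
             params = c(alpha = alpha, b0 = log(1e-4)),
             baseline = list(g_average = 1), twin_id = twin_id)
}

make_case <- function(dose_msv = 100, exposure_year = 2000, birth = 1950,
                      diagnosis = 2008, n_exposures = 1, sex = "male",
                      group = "TEST", duration_hours = NULL) {
  exposures <- lapply(seq_len(n_exposures), function(i) {
    exposure_event(exposure_year, list(dist = "fixed", value = dose_msv),
                   duration_hours = duration_hours)
  })
  case_spec(group, sex, birth, diagnosis, exposures)
}

single_model_set <- function(model, group = "TEST") {
  model_set(paste0(model$id, "-set"), group, list(model))
}

# Closed-form mixed-transfer assigned share for a single fixed exposure,
# built from the exported primitives (independent of the engine loop).
closed_form_z <- function(model, pop, case, f = 0.5) {
  a <- case$diagnosis_year - case$birth_year
  lam0 <- baseline_rate(pop, case$sex, a, case$diagnosis_year)
  terms <- vapply(case$exposures, function(ex) {
    e_i <- ex$year - case$birth_year
    t_raw <- case$diagnosis_year - ex$year
    t_eff <- capped_time_since_exposure(model$disease_class, t_raw)
    a_eff <- e_i + t_eff
    d <- ex$dose$value / 1000
    x <- excess(model, d, case$sex, a_eff, e_i)
    lat <- if (model$disease_class == "solid") list(t0 = 3.5, eta = 6.25)
           else list(t0 = 1.5, eta = 7.66)
    x <- x * latency_factor(t_raw, lat$t0, lat$eta)
    lam0m <- model_baseline(model, case$sex, a, 1945 + t_eff)
    h_m <- if (model$kind == "ERR") lam0m * x else ear_to_rate(x)
    c(h_m, lam0 / lam0m)
  }, numeric(2))
  h <- sum(transferred_excess(terms[1, ], f, terms[2, ]))
  assigned_share(h, lam0)
}
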