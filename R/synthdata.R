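#' Generate a synthetic target-population incidence table
#'
#' Emulates a registry table: a log-linear rate surface in attained age and
#' calendar year, a population pyramid shrinking with age, and Poisson case
#' counts per stratum. Ages are grouped in 5-year bands.
#'
#' @param years Calendar years covered (contiguous).
#' @param age_max Upper age bound (multiple of 5).
#' @param base_rate Rate at the reference age (70) and first year, PY^-1.
#' @param age_power Power of attained age relative to 70.
#' @param year_trend Log-linear trend per calendar year.
#' @param py_scale Person-years in the youngest age band.
#' @param sex_ratio Female/male rate ratio.
#' @return A [population_table()] tibble.
#' @export
generate_population_table <- function(years = 1995:2014, age_max = 100,
                                      base_rate = 2e-4, age_power = 4,
                                      year_trend = 0.005, py_scale = 3e6,
                                      sex_ratio = 0.8) {
  grid <- tidyr::expand_grid(
    sex = c("male", "female"),
    age_low = seq(0, age_max - 5, by = 5),
    year = years)
  grid <- grid |>
    mutate(age_high = .data$age_low + 4,
           mid = .data$age_low + 2.5,
           person_years = round(py_scale * exp(-.data$mid / 80)),
           rate = base_rate * pmax(.data$mid / 70, 0.05)^age_power *
             exp(year_trend * (.data$year - years[1])) *
             ifelse(.data$sex == "female", sex_ratio, 1),
           cases = rpois(dplyr::n(), .data$rate * .data$person_years)) |>
    select("sex", "age_low", "age_high", "year", "cases", "person_years")
  population_table(grid)
}

#' Generate grouped cohort cells from a known true model
#'
#' Builds a stratified person-year table over doses, sexes, ages and
#' city/in-city strata and draws the case count of each cell from a Poisson
#' distribution with mean equal to the true model rate times the cell
#' person-years. Used for parameter-recovery simulation studies.
#'
#' @param spec A [fit_spec()] describing the true model form.
#' @param true_params Named parameter vector of the generating model.
#' @param doses Dose grid in Gy (default 0--4 Gy).
#' @param ages Attained-age midpoints.
#' @param ages_at_exposure Age-at-exposure midpoints (filtered to be below
#'   the attained age).
#' @param py Person-years per cell.
#' @param cohort_strata If `TRUE`, cross with city (-1/+1) and in-city (0/1)
#'   strata.
#' @return A [cohort_cells()] tibble.
#' @export
generate_cohort_cells <- function(spec, true_params,
                                  doses = c(0, 0.1, 0.5, 1, 2, 4),
                                  ages = c(40, 55, 70, 85),
                                  ages_at_exposure = 30,
                                  py = 1e5, cohort_strata = FALSE) {
  grid <- tidyr::expand_grid(s = c(-1, 1), a = ages, e = ages_at_exposure,
                             d = doses,
                             c = if (cohort_strata) c(-1, 1) else 0,
                             ic = if (cohort_strata) c(0, 1) else 0)
  grid <- grid[grid$a >= grid$e, ]
  grid$py <- py
  grid$n <- 0L
  cells <- cohort_cells(grid)
  mu <- expected_counts(spec, true_params, cells)
  if (any(mu < 0)) abort("true model produces negative expected counts")
  cells$n <- rpois(nrow(cells), mu)
  cells
}

# Back-compute an illustrative standard error from a printed Wald p-value.
se_from_p <- function(coef, p) abs(coef) / qnorm(1 - min(max(p, 1e-3), 0.9999) / 2)

example_solid_row <- function(id, kind, constant, p_const, phi = NULL,
                              p_phi = NULL, gamma = NULL, psi = NULL,
                              p_psi = NULL, baseline_b0, baseline_b_age,
                              aic = 0) {
  params <- c(beta = constant)
  ses <- c(beta = se_from_p(constant, p_const))
  modifiers <- list()
  if (!is.null(phi)) {
    params <- c(params, phi = phi)
    ses <- c(ses, phi = se_from_p(phi, p_phi))
    modifiers$attained_age <- TRUE
  }
  if (!is.null(psi)) {
    params <- c(params, psi = psi)
    ses <- c(ses, psi = se_from_p(psi, p_psi))
    modifiers$age_at_exposure <- TRUE
  }
  form <- "linear"
  if (!is.null(gamma)) {
    form <- "power"
    params <- c(params, gamma = gamma)
    ses <- c(ses, gamma = se_from_p(gamma, 1e-3))
  }
  params <- c(params, b0 = baseline_b0, b_age = baseline_b_age)
  ses <- c(ses, b0 = 0.05, b_age = 0.1)
  risk_model(
    id = id, kind = kind, disease_class = "solid",
    dose_response = list(form = form), modifiers = modifiers,
    params = params,
    covariance = diag(ses^2, nrow = length(ses)),
    aic = aic, baseline = list(g_average = 1), lss_cohort = TRUE)
}

#' Packaged example model sets
#'
#' Ready-to-run ERR/EAR model pairs for the grouped solid-cancer sites
#' (DIG, URI, GNF1, GNF2, GNM, BCNS, SKIN, REM) built from the published
#' grouped-model constants, attained-age powers, dose exponents and
#' age-at-exposure modifiers, plus a synthetic hematopoietic set ("HEM")
#' with a quadratic model and its linear twin for twin-rule exercises.
#'
#' The published tables do not include covariance matrices or baselines:
#' the covariances here are illustrative diagonals back-computed from the
#' printed Wald p-values, and the baselines are synthetic log-linear rates
#' (intercept at a typical registry scale, power of attained age). They are
#' suitable for demonstrations and structural tests, not for claims
#' adjudication.
#'
#' @return Named list of [model_set()]s.
#' @export
example_model_sets <- function() {
  # AIC differences chosen to reproduce the published MMI weights where
  # stated (e.g. DIG ERR 71% / EAR 29%).
  aic_pair <- function(w_first) c(0, -2 * log((1 - w_first) / w_first))
  sets <- list()
  dig_aics <- aic_pair(0.71)
  sets$DIG <- model_set("DIG-example", "DIG", list(
    example_solid_row("DIG-ERR", "ERR", 0.24, 0.001, phi = -3.04, p_phi = 1e-3,
                      baseline_b0 = log(15e-4), baseline_b_age = 4,
                      aic = dig_aics[1]),
    example_solid_row("DIG-EAR", "EAR", 6.85, 1e-3, phi = 2.26, p_phi = 1e-3,
                      baseline_b0 = log(15e-4), baseline_b_age = 4,
                      aic = dig_aics[2])))
  uri_aics <- aic_pair(0.47)
  sets$URI <- model_set("URI-example", "URI", list(
    example_solid_row("URI-ERR", "ERR", 1.21, 1e-3,
                      baseline_b0 = log(4e-4), baseline_b_age = 4.5,
                      aic = uri_aics[1]),
    example_solid_row("URI-EAR", "EAR", 4.19, 1e-3, phi = 3.63, p_phi = 1e-3,
                      baseline_b0 = log(4e-4), baseline_b_age = 4.5,
                      aic = uri_aics[2])))
  gnf1_aics <- aic_pair(0.43)
  sets$GNF1 <- model_set("GNF1-example", "GNF1", list(
    example_solid_row("GNF1-ERR", "ERR", 0.06, 0.68,
                      baseline_b0 = log(2e-4), baseline_b_age = 1,
                      aic = gnf1_aics[1]),
    example_solid_row("GNF1-EAR", "EAR", 0.57, 0.4,
                      baseline_b0 = log(2e-4), baseline_b_age = 1,
                      aic = gnf1_aics[2])))
  gnf2_aics <- aic_pair(0.72)
  sets$GNF2 <- model_set("GNF2-example", "GNF2", list(
    example_solid_row("GNF2-ERR", "ERR", 0.35, 0.12,
                      baseline_b0 = log(3e-4), baseline_b_age = 2.5,
                      aic = gnf2_aics[1]),
    example_solid_row("GNF2-EAR", "EAR", 0.49, 0.3,
                      baseline_b0 = log(3e-4), baseline_b_age = 2.5,
                      aic = gnf2_aics[2])))
  gnm_aics <- aic_pair(0.76 / (0.76 + 0.05))  # dominant ERR vs EAR leaf
  sets$GNM <- model_set("GNM-example", "GNM", list(
    example_solid_row("GNM-ERR", "ERR", 0.12, 0.56,
                      baseline_b0 = log(8e-4), baseline_b_age = 6,
                      aic = gnm_aics[1]),
    example_solid_row("GNM-EAR", "EAR", 0.20, 0.37, phi = -3.7, p_phi = 0.3,
                      baseline_b0 = log(8e-4), baseline_b_age = 6,
                      aic = gnm_aics[2])))
  bcns_aics <- aic_pair(0.58)
  sets$BCNS <- model_set("BCNS-example", "BCNS", list(
    example_solid_row("BCNS-ERR", "ERR", 0.23, 0.23, phi = -2.97, p_phi = 0.009,
                      baseline_b0 = log(0.8e-4), baseline_b_age = 1.5,
                      aic = bcns_aics[1]),
    example_solid_row("BCNS-EAR", "EAR", 0.46, 0.046,
                      baseline_b0 = log(0.8e-4), baseline_b_age = 1.5,
                      aic = bcns_aics[2])))
  skin_aics <- aic_pair(0.72)
  sets$SKIN <- model_set("SKIN-example", "SKIN", list(
    example_solid_row("SKIN-ERR", "ERR", 0.71, 0.018, gamma = 1.55,
                      psi = -0.89, p_psi = 1e-3,
                      baseline_b0 = log(5e-4), baseline_b_age = 5,
                      aic = skin_aics[1]),
    example_solid_row("SKIN-EAR", "EAR", 1.1, 0.021, gamma = 1.60,
                      phi = 3.65, p_phi = 1e-3, psi = -0.75, p_psi = 1e-3,
                      baseline_b0 = log(5e-4), baseline_b_age = 5,
                      aic = skin_aics[2])))
  rem_aics <- aic_pair(0.67)
  sets$REM <- model_set("REM-example", "REM", list(
    example_solid_row("REM-ERR", "ERR", 0.25, 0.20, phi = -2.77, p_phi = 0.02,
                      baseline_b0 = log(1.5e-4), baseline_b_age = 2,
                      aic = rem_aics[1]),
    example_solid_row("REM-EAR", "EAR", 0.60, 0.03,
                      baseline_b0 = log(1.5e-4), baseline_b_age = 2,
                      aic = rem_aics[2])))
  # Synthetic hematopoietic quadratic + linear twin pair (twin-rule tests).
  hem_base <- list(g_average = 1)
  hem_quad <- risk_model(
    id = "HEM-QUAD", kind = "ERR", disease_class = "hematopoietic",
    dose_response = list(form = "quadratic"),
    params = c(alpha = 1.0, b0 = log(0.5e-4), b_age = 1),
    covariance = diag(c(0.2, 0.05, 0.1)^2),
    aic = 0, baseline = hem_base, twin_id = "HEM-LIN", lss_cohort = TRUE)
  hem_lin <- risk_model(
    id = "HEM-LIN", kind = "ERR", disease_class = "hematopoietic",
    dose_response = list(form = "linear"),
    params = c(beta = 1.0, b0 = log(0.5e-4), b_age = 1),
    covariance = diag(c(0.2, 0.05, 0.1)^2),
    aic = 4.39, baseline = hem_base, lss_cohort = TRUE)
  sets$HEM <- model_set("HEM-synthetic", "HEM3", list(hem_quad, hem_lin),
    tree = weight_tree(list(list(weight = 1, model_ids = c("HEM-QUAD", "HEM-LIN"),
                                 aics = c(0, 4.39)))))
  sets
}

#' Generate a synthetic smoking-prevalence table
#'
#' Stand-in for national smoking statistics, used when a lung-cancer case
#' has unknown smoking status: per sex, the probabilities of never/current/
#' past smoking and a normal intensity distribution (cigarettes per day).
#' Probabilities sum to 1 within each sex.
#'
#' @param p_never,p_current Named (male/female) probabilities; past smoking
#'   takes the remainder.
#' @param cpd_mean,cpd_sd Intensity distribution for (ex-)smokers.
#' @return Tibble with columns sex, status, prob, cpd_mean, cpd_sd.
#' @export
generate_smoking_prevalence <- function(p_never = c(male = 0.4, female = 0.55),
                                        p_current = c(male = 0.35, female = 0.25),
                                        cpd_mean = 15, cpd_sd = 8) {
  purrr::map_dfr(c("male", "female"), function(sx) {
    pn <- p_never[[sx]]; pc <- p_current[[sx]]
    tibble(sex = sx, status = c("never", "current", "past"),
           prob = c(pn, pc, 1 - pn - pc),
           cpd_mean = c(0, cpd_mean, cpd_mean),
           cpd_sd = c(0, cpd_sd, cpd_sd))
  })
}
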