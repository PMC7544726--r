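test_that("assigned share is the excess fraction of the total rate", {
  expect_identical(assigned_share(0, 1e-4), 0)
  expect_equal(assigned_share(1e-4, 1e-4), 0.5)
  expect_equal(assigned_share(1e-4, 2e-4), 1 / 3)
  expect_identical(assigned_share(-5e-4, 1e-4), 0)  # negative excess floors Z
  expect_error(assigned_share(1e-4, 0), "positive")
})

test_that("time since exposure is capped to the follow-up window", {
  expect_equal(capped_time_since_exposure("solid", 60), 53)
  expect_equal(capped_time_since_exposure("solid", 20), 20)
  expect_equal(capped_time_since_exposure("solid", 1), 1)  # no solid floor
  expect_equal(capped_time_since_exposure("hematopoietic", 3), 5)
  expect_equal(capped_time_since_exposure("hematopoietic", 60), 56)
  expect_equal(capped_time_since_exposure("hematopoietic", 30), 30)
})

test_that("multiple exposures combine per the mixed-transfer formula", {
  # single exposure with B = 1 reduces to the basic definition
  expect_equal(combine_exposures(1e-4, 1, 0.7, 2e-4),
               assigned_share(1e-4, 2e-4))
  # two equal exposures under additive transfer
  expect_equal(combine_exposures(rep(1e-4, 2), rep(2, 2), 0, 3e-4),
               2e-4 / (3e-4 + 2e-4))
  # general plug-in
  h <- c(1e-4, 5e-5); B <- c(2, 0.5); f <- 0.3; lam0 <- 4e-4
  s <- (1 - f) * sum(h) + f * sum(h * B)
  expect_equal(combine_exposures(h, B, f, lam0), s / (lam0 + s))
  # monotone non-decreasing in each h and each B for f > 0
  base <- combine_exposures(h, B, f, lam0)
  expect_gte(combine_exposures(h + c(1e-5, 0), B, f, lam0), base)
  expect_gte(combine_exposures(h, B + c(0.5, 0), f, lam0), base)
})

test_that("the twin rule takes the linear model at low doses", {
  expect_equal(twin_rule(0.3, 0.3), 0.3)
  # quadratic alpha = 1/Gy^2 vs linear beta = 1/Gy twin at 0.1 Gy:
  # twin excess 0.1 > quadratic 0.01, so the twin's Z wins
  quad <- make_quadratic_model(alpha = 1)
  lin <- risk_model("LIN", "ERR", "hematopoietic", list(form = "linear"),
                    params = c(beta = 1, b0 = log(1e-4)),
                    baseline = list(g_average = 1))
  lam0 <- 1e-4
  z_q <- assigned_share(lam0 * dose_term(quad, 0.1), lam0)
  z_l <- assigned_share(lam0 * dose_term(lin, 0.1), lam0)
  expect_gt(z_l, z_q)
  expect_equal(twin_rule(z_q, z_l), z_l)
})

test_that("the maximum-ERR rule is a pointwise maximum over the group", {
  expect_equal(max_err_rule(0.4), 0.4)
  expect_equal(max_err_rule(list(c(1, 2, 3), c(2, 1, 1))), c(2, 2, 3))
  # crossing curves flatten out at the pointwise maximum
  x <- seq(0, 30, by = 1)
  rising <- 0.1 + 0.01 * x
  falling_peak <- 0.5 * x * exp(-x / 5)
  combined <- max_err_rule(list(rising, falling_peak))
  expect_true(all(combined >= rising & combined >= falling_peak))
})

test_that("a frozen-uncertainty run equals the closed-form value exactly", {
  pop <- make_pop()
  m <- make_err_model(beta = 0.5, phi = -2)
  case <- make_case(dose_msv = 200)
  zd <- run_case(case, single_model_set(m), pop,
                 frozen_config(iterations = 30), seed = 2)
  expect_equal(length(unique(zd$z)), 1L)
  expect_equal(zd$z[1], closed_form_z(m, pop, case), tolerance = 1e-12)
  # multi-exposure frozen case
  case2 <- case_spec("TEST", "female", 1945, 2009, list(
    exposure_event(1980, list(dist = "fixed", value = 150)),
    exposure_event(1995, list(dist = "fixed", value = 50))))
  zd2 <- run_case(case2, single_model_set(m), pop,
                  frozen_config(iterations = 10), seed = 3)
  expect_equal(zd2$z[1], closed_form_z(m, pop, case2), tolerance = 1e-12)
})

test_that("zero-dose exposures give an identically zero assigned share", {
  pop <- make_pop()
  m <- make_err_model()
  case <- make_case(dose_msv = 0)
  zd <- run_case(case, single_model_set(m), pop,
                 run_config(iterations = 100), seed = 4)
  expect_true(all(zd$z == 0))
})

test_that("runs are deterministic under a fixed seed", {
  pop <- make_pop()
  m <- make_err_model(cov = diag(c(0.1, 0.02, 0.1)^2))
  case <- make_case()
  z1 <- run_case(case, single_model_set(m), pop,
                 run_config(iterations = 200), seed = 99)
  z2 <- run_case(case, single_model_set(m), pop,
                 run_config(iterations = 200), seed = 99)
  expect_identical(z1$z, z2$z)
  z3 <- run_case(case, single_model_set(m), pop,
                 run_config(iterations = 200), seed = 100)
  expect_false(identical(z1$z, z3$z))
})

test_that("stratified MMI reproduces the documented realization split", {
  pop <- make_pop()
  m1 <- make_err_model(id = "A", beta = 0.5)
  m2 <- make_err_model(id = "B", beta = 0.3)
  m1$aic <- 0; m2$aic <- 2 * log(0.6 / 0.4)
  set <- model_set("pair", "TEST", list(m1, m2))
  expect_equal(unname(set$tree$leaves$weight), c(0.6, 0.4), tolerance = 1e-12)
  case <- make_case()
  zd <- run_case(case, set, pop, run_config(iterations = 1000), seed = 5)
  counts <- table(zd$models)
  expect_identical(as.integer(counts[c("A", "B")]), c(600L, 400L))
})

test_that("every sampled Z lies in [0, 1) under randomised inputs", {
  pop <- make_pop()
  withr::with_seed(77, {
    for (i in 1:5) {
      m <- make_err_model(beta = runif(1, 0.05, 3), phi = runif(1, -4, 1),
                          cov = diag(c(0.3, 0.05, 0.2, 0.5)^2))
      case <- make_case(dose_msv = runif(1, 10, 3000),
                        exposure_year = sample(1975:2005, 1),
                        duration_hours = sample(c(NA, 100), 1))
      case$exposures[[1]]$dose <- list(dist = "lognormal",
                                       gm = case$exposures[[1]]$dose$value,
                                       gsd = 1.5)
      zd <- run_case(case, single_model_set(m), pop,
                     run_config(iterations = 300), seed = i)
      expect_true(all(zd$z >= 0 & zd$z < 1))
      expect_true(all(diff(zd$percentiles$value) >= 0))
    }
  })
})

test_that("twin models stabilise fractionated quadratic exposures", {
  pop <- make_pop()
  quad <- make_quadratic_model(alpha = 1, twin_id = "LIN")
  lin <- risk_model("LIN", "ERR", "hematopoietic", list(form = "linear"),
                    params = c(beta = 1, b0 = log(1e-4)),
                    baseline = list(g_average = 1), aic = 10)
  set <- model_set("twin-set", "TEST", list(quad, lin))
  # the default tree excludes the twin from selection
  expect_identical(set$tree$leaves$model_id, "QUAD")
  frac <- case_spec("TEST", "male", 1950, 2008,
                    lapply(1:10, function(i)
                      exposure_event(1990, list(dist = "fixed", value = 100))))
  single <- make_case(dose_msv = 1000, exposure_year = 1990,
                      birth = 1950, diagnosis = 2008)
  z_frac <- run_case(frac, set, pop, frozen_config(iterations = 5), seed = 1)
  z_single <- run_case(single, set, pop, frozen_config(iterations = 5), seed = 1)
  # without the twin, 10 x 100 mGy under a pure quadratic response would give
  # one tenth of the single-exposure excess; the linear twin dominates at
  # 100 mGy and makes the fractionated Z equal the single-dose linear Z
  no_twin <- model_set("solo", "TEST", list(make_quadratic_model(alpha = 1)))
  z_frac_solo <- run_case(frac, no_twin, pop, frozen_config(iterations = 5),
                          seed = 1)
  expect_gt(z_frac$z[1], z_frac_solo$z[1])
  expect_equal(z_frac$z[1], closed_form_z(lin, pop, frac), tolerance = 1e-12)
  expect_gt(z_single$z[1], 0)
})

test_that("an EAR model feeds the absolute excess through unit conversion", {
  pop <- make_pop()
  ear <- risk_model("EAR-1", "EAR", "solid", list(form = "linear"),
                    params = c(beta = 4.19, b0 = log(2e-4), b_age = 3),
                    baseline = list(g_average = 1))
  case <- make_case(dose_msv = 500)
  zd <- run_case(case, single_model_set(ear), pop,
                 frozen_config(iterations = 5), seed = 6)
  a <- 58; e <- 50; t <- 8
  lam0 <- baseline_rate(pop, "male", a, 2008)
  lam0m <- model_baseline(ear, "male", a, 1945 + t)
  h_m <- ear_to_rate(excess(ear, 0.5, "male", e + t, e)) *
    latency_factor(t, 3.5, 6.25)
  h <- transferred_excess(h_m, 0.5, lam0 / lam0m)
  expect_equal(zd$z[1], assigned_share(h, lam0), tolerance = 1e-12)
})

test_that("generic-transfer models use the sampled baseline ratio", {
  pop <- make_pop()
  gen <- risk_model("GEN", "ERR", "solid", list(form = "linear"),
                    params = c(beta = 1))  # no baseline
  case <- make_case(dose_msv = 300)
  zd <- run_case(case, single_model_set(gen), pop,
                 frozen_config(iterations = 5), seed = 7)
  # frozen mode pins B = 1: Z = ERR*lam0 / (lam0 + ERR*lam0) = ERR/(1+ERR)
  err <- excess(gen, 0.3, "male", 58, 50) * latency_factor(8, 3.5, 6.25)
  expect_equal(zd$z[1], err / (1 + err), tolerance = 1e-12)
  # sampled mode varies B within [1/3, 3] around the frozen value
  zd2 <- run_case(case, single_model_set(gen), pop,
                  run_config(iterations = 500, transfer = "fixed",
                             sample_params = FALSE, sample_latency = FALSE,
                             sample_dose = FALSE, sample_baseline = FALSE,
                             cohort_factors = FALSE, dref = FALSE),
                  seed = 8)
  expect_gt(length(unique(zd2$z)), 100)
})

test_that("unknown smoking status samples intensity from the prevalence table", {
  pop <- make_pop()
  smoke <- risk_model("SMK", "ERR", "solid", list(form = "linear"),
                      modifiers = list(smoking = "loglinear"),
                      params = c(beta = 1, theta = -0.05, b0 = log(2e-4)),
                      baseline = list(g_average = 1))
  case <- make_case(dose_msv = 500)
  case$smoking <- list(status = "unknown")
  prev <- generate_smoking_prevalence()
  cfg <- run_config(iterations = 400, transfer = "fixed",
                    sample_params = FALSE, sample_latency = FALSE,
                    sample_dose = FALSE, sample_baseline = FALSE,
                    cohort_factors = FALSE, dref = FALSE,
                    smoking_prevalence = prev)
  zd <- run_case(case, single_model_set(smoke), pop, cfg, seed = 9)
  # never-smokers keep the baseline ERR; smokers reduce it via theta < 0
  z_never <- max(zd$z)
  expect_gt(mean(zd$z < z_never), 0.2)  # a substantial smoking fraction
  case$smoking <- list(status = "never")
  zd_never <- run_case(case, single_model_set(smoke), pop, cfg, seed = 10)
  expect_equal(length(unique(zd_never$z)), 1L)
  expect_equal(zd_never$z[1], z_never, tolerance = 1e-12)
})

test_that("a maximum-ERR group takes the larger model inside the engine", {
  pop <- make_pop()
  lo <- make_err_model(id = "LO", beta = 0.2, max_group = "grp")
  hi <- make_err_model(id = "HI", beta = 0.9, max_group = "grp")
  hi$aic <- 50  # selection lands on LO, the group still lifts it to HI
  set <- model_set("maxset", "TEST", list(lo, hi))
  case <- make_case(dose_msv = 400)
  zd <- run_case(case, set, pop, frozen_config(iterations = 5), seed = 1)
  expect_equal(zd$z[1], closed_form_z(hi, pop, case), tolerance = 1e-12)
  expect_gt(zd$z[1], closed_form_z(lo, pop, case))
})

test_that("indoor radon exposure scales with concentration times duration", {
  pop <- make_pop()
  radon <- risk_model("RN", "ERR", "solid", list(form = "linear"),
                      params = c(beta = 1e-6),  # per (Bq/m3 x hour)
                      radiation_class = "radon_indoor")
  mk <- function(hours) {
    case_spec("TEST", "male", 1950, 2008, list(
      exposure_event(1990, list(dist = "fixed", value = 300),
                     duration_hours = hours,
                     radiation_class = "radon_indoor")))
  }
  z1 <- run_case(mk(1000), single_model_set(radon), pop,
                 frozen_config(iterations = 3), seed = 1)$z[1]
  z2 <- run_case(mk(2000), single_model_set(radon), pop,
                 frozen_config(iterations = 3), seed = 1)$z[1]
  err <- function(hours) 300 * hours * 1e-6 * latency_factor(18, 3.5, 6.25)
  expect_equal(z1, err(1000) / (1 + err(1000)), tolerance = 1e-12)
  expect_equal(z2, err(2000) / (1 + err(2000)), tolerance = 1e-12)
  # duration is mandatory for indoor radon
  expect_error(exposure_event(1990, 300, radiation_class = "radon_indoor"),
               "duration_hours")
})

test_that("iteration limits and group mismatches are rejected", {
  expect_error(run_config(iterations = 60000), "50,000")
  expect_error(run_config(iterations = 0), "50,000")
  pop <- make_pop()
  m <- make_err_model()
  case <- make_case(group = "OTHER")
  expect_error(run_case(case, single_model_set(m), pop,
                        run_config(iterations = 10), seed = 1),
               "does not match")
})

test_that("summaries report the requested percentiles and intervals", {
  zc <- z_distribution(rep(0.25, 100))
  expect_true(all(zc$percentiles$value == 0.25))
  expect_equal(glance(zc)$mean, 0.25)
  half <- z_distribution(rep(c(0, 0.9999), each = 5000))
  expect_equal(glance(half)$mean, 0.49995)
  withr::with_seed(12, u <- runif(1e5, 0, 0.999))
  zu <- z_distribution(u)
  q975 <- zu$percentiles$value[zu$percentiles$percentile == 97.5]
  se <- sqrt(0.975 * 0.025 / 1e5) / 1  # order-statistic SE on uniform scale
  expect_lt(abs(q975 - 0.975 * 0.999), 3 * se + 1e-3)
  expect_error(z_distribution(c(0.2, 1.0)), "\\[0, 1\\)")
  expect_error(z_distribution(numeric(0)), "non-empty")
  td <- tidy(zu)
  expect_true(all(c("percentile", "value") %in% names(td)))
  p <- autoplot(zu)
  expect_s3_class(p, "ggplot")
})
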