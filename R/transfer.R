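#' Map a time since exposure onto the cohort's calendar timeframe
#'
#' Cohort-based model baselines are evaluated at the calendar year of the
#' Life Span Study that corresponds to the individual's time since exposure,
#' anchored at the 1945 detonations: an exposure in 1980 diagnosed in 2010
#' (30 years later) maps to cohort year 1975.
#'
#' @param exposure_year Calendar year of the exposure.
#' @param diagnosis_year Calendar year of diagnosis; must not precede the
#'   exposure.
#' @return Cohort calendar year, `1945 + (diagnosis_year - exposure_year)`.
#' @export
lss_calendar_year <- function(exposure_year, diagnosis_year) {
  if (any(diagnosis_year < exposure_year)) {
    abort("diagnosis year must not precede exposure year")
  }
  1945 + (diagnosis_year - exposure_year)
}

#' Baseline ratio between target population and model
#'
#' `B = lambda0 / lambda0m`: the target-population baseline rate divided by
#' the cohort-model baseline at matched sex and attained age and the mapped
#' calendar year.
#'
#' @param target_rate Target-population baseline rate (PY^-1), positive.
#' @param model_rate Model baseline rate (PY^-1), positive.
#' @return Positive ratio.
#' @export
baseline_ratio <- function(target_rate, model_rate) {
  if (any(target_rate <= 0) || any(model_rate <= 0)) {
    abort("baseline rates must be strictly positive")
  }
  target_rate / model_rate
}

#' Sample a generic baseline ratio
#'
#' For models without a usable baseline parametrisation (e.g. pooled-cohort
#' breast or smoking-adjusted lung models) the baseline ratio is sampled
#' log-uniformly between 1/3 and 3, i.e. `log(B) ~ U(log 1/3, log 3)`; the
#' median and geometric mean are 1.
#'
#' @param n Number of draws.
#' @return Positive draws in [1/3, 3].
#' @export
generic_baseline_ratio <- function(n = 1) {
  exp(runif(n, log(1 / 3), log(3)))
}

#' Sample the transfer weight f
#'
#' The weight of the multiplicative component in the mixed risk transfer.
#' With no prior knowledge f is uniform on (0, 1) (maximum entropy); for
#' best-estimate comparisons a fixed f = 0.5 is available.
#'
#' @param n Number of draws.
#' @param mode `"uniform"` (default) or `"fixed"` (returns 0.5 exactly).
#' @param fixed_value Value used in `"fixed"` mode (default 0.5).
#' @return Draws in [0, 1].
#' @export
sample_transfer_weight <- function(n = 1, mode = c("uniform", "fixed"),
                                   fixed_value = 0.5) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(rep(fixed_value, n))
  runif(n)
}

#' Mixed additive/multiplicative transferred excess rate
#'
#' `h = h_m * (1 - f + f * B)`: `f = 0` keeps the absolute excess rate
#' (additive transfer), `f = 1` scales it by the baseline ratio
#' (multiplicative transfer).
#'
#' @param h_m Model excess rate (PY^-1).
#' @param f Transfer weight in [0, 1].
#' @param B Baseline ratio, positive.
#' @return Transferred excess rate.
#' @export
transferred_excess <- function(h_m, f, B) {
  if (any(f < 0) || any(f > 1)) abort("transfer weight must lie in [0, 1]")
  if (any(B <= 0)) abort("baseline ratio must be positive")
  h_m * (1 - f + f * B)
}
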