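#' Construct/validate a target-population incidence table
#'
#' A tibble keyed by sex, 5-year age group and calendar year, with observed
#' case counts and person-years; the rate column is derived as
#' `cases / person_years`. Registry-style tables in this layout are the
#' source of the target-population baseline rate.
#'
#' @param df Data frame with columns `sex` (`"male"`/`"female"`), `age_low`,
#'   `age_high`, `year`, `cases` (non-negative integers), `person_years`
#'   (positive); an optional `rate` column is recomputed.
#' @return A validated tibble of class `population_table`.
#' @export
population_table <- function(df) {
  req <- c("sex", "age_low", "age_high", "year", "cases", "person_years")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("population table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (any(df$person_years <= 0)) abort("person_years must be positive")
  if (any(df$cases < 0) || any(df$cases != round(df$cases))) {
    abort("cases must be non-negative integers")
  }
  if (any(df$age_high < df$age_low)) abort("age_high must be >= age_low")
  df$sex <- tolower(as.character(df$sex))
  if (!all(df$sex %in% c("male", "female"))) abort("sex must be male/female")
  df$rate <- df$cases / df$person_years
  yrs <- sort(unique(df$year))
  if (length(yrs) > 1 && !all(diff(yrs) == 1)) {
    abort("calendar years must be contiguous")
  }
  class(df) <- c("population_table", class(df))
  df
}

#' Read a population table from delimited text
#'
#' @param path CSV file with the [population_table()] columns.
#' @return A `population_table` tibble.
#' @export
read_population_table <- function(path) {
  population_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

pop_lookup <- function(table, s, a, year) {
  sex_chr <- if (is.numeric(s)) c("male", "female")[(s + 3) / 2] else tolower(s)
  last_year <- max(table$year)
  if (year < min(table$year)) {
    abort("diagnosis year precedes population-table coverage")
  }
  year <- min(year, last_year)  # later years fall back to the last available
  row <- dplyr::filter(table, .data$sex == sex_chr, .data$year == !!year,
                       .data$age_low <= !!a, .data$age_high >= !!a)
  if (nrow(row) != 1) {
    abort(sprintf("no unique population record for sex=%s age=%s year=%s",
                  sex_chr, a, year))
  }
  row
}

#' Target-population baseline rate
#'
#' Exact lookup of the registry rate for the age group containing the
#' attained age; diagnosis years beyond the table's coverage use the last
#' available year's rates.
#'
#' @param table A [population_table()].
#' @param s Sex (`"male"`/`"female"` or -1/+1).
#' @param a Attained age (years).
#' @param year Calendar year of diagnosis.
#' @return Rate in PY^-1.
#' @export
baseline_rate <- function(table, s, a, year) {
  pop_lookup(table, s, a, year)$rate
}

#' Sample the target-population baseline rate
#'
#' Propagates registry sampling uncertainty by drawing the case count from a
#' Poisson distribution with mean equal to the observed count and dividing
#' by the stratum person-years. Zero counts are handled by flooring both the
#' Poisson mean and the sampled count at 0.5, so the baseline cannot
#' degenerate to zero (which would force the assigned share to 1); for the
#' large counts typical of registry strata the floor is never active and the
#' sampled mean equals the point rate.
#'
#' @inheritParams baseline_rate
#' @param n Number of draws.
#' @return Sampled rates in PY^-1, strictly positive.
#' @export
sample_baseline <- function(table, s, a, year, n = 1) {
  row <- pop_lookup(table, s, a, year)
  mu <- max(row$cases, 0.5)
  pmax(rpois(n, mu), 0.5) / row$person_years
}
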