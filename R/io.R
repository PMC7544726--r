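#' Read a case specification from JSON
#'
#' Canonical case format: an object with `cancer_group`, `sex`,
#' `birth_year`, `diagnosis_year`, optional `smoking` and an `exposures`
#' array, each exposure carrying `year`, a `dose` object (`dist` plus its
#' parameters, in mSv for low-LET), optional `duration_hours`,
#' `radiation_class` and `organ_class`.
#'
#' @param path JSON file path.
#' @return A [case_spec()].
#' @export
read_case <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  exposures <- map(x$exposures, function(ex) {
    exposure_event(year = ex$year, dose = ex$dose,
                   duration_hours = ex$duration_hours,
                   radiation_class = ex$radiation_class %||% "lowLET",
                   organ_class = ex$organ_class %||% "internal")
  })
  case_spec(cancer_group = x$cancer_group, sex = x$sex,
            birth_year = x$birth_year, diagnosis_year = x$diagnosis_year,
            exposures = exposures, smoking = x$smoking)
}

#' Write a case specification to JSON
#'
#' @param case A [case_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_case <- function(case, path) {
  out <- unclass(case)
  out$exposures <- map(case$exposures, unclass)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

model_to_config <- function(m) {
  list(id = m$id, kind = m$kind, disease_class = m$disease_class,
       dose_response = m$dose_response,
       modifiers = m$modifiers,
       params = as.list(m$params),
       covariance = list(names = names(m$params),
                         values = as.numeric(t(m$covariance))),
       aic = m$aic, twin_id = m$twin_id, max_group = m$max_group,
       lss_cohort = m$lss_cohort, radiation_class = m$radiation_class,
       baseline = m$baseline)
}

config_to_model <- function(cfg) {
  p <- length(cfg$params)
  cov <- matrix(as.numeric(unlist(cfg$covariance$values)), p, p, byrow = TRUE)
  cov <- (cov + t(cov)) / 2  # serialisation round-trip can break symmetry
  risk_model(id = cfg$id, kind = cfg$kind, disease_class = cfg$disease_class,
             dose_response = cfg$dose_response,
             modifiers = cfg$modifiers %||% list(),
             params = unlist(cfg$params), covariance = cov,
             aic = cfg$aic %||% 0, twin_id = cfg$twin_id,
             max_group = cfg$max_group,
             lss_cohort = isTRUE(cfg$lss_cohort),
             radiation_class = cfg$radiation_class %||% "lowLET",
             baseline = cfg$baseline)
}

#' Write a model set to a YAML config file
#'
#' Serialises every model (parameters, row-major covariance, AIC, baseline,
#' twin links) together with the weight tree.
#'
#' @param set A [model_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_set <- function(set, path) {
  cfg <- list(id = set$id, cancer_group = set$cancer_group,
              models = map(unname(set$models), model_to_config),
              tree = map(set$tree$branches, function(b) {
                list(weight = b$weight, model_ids = as.list(b$model_ids),
                     aics = as.list(b$aics))
              }))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a model set from a YAML config file
#'
#' @param path YAML file written by [write_model_set()] (or hand-authored
#'   in the same layout).
#' @return A [model_set()].
#' @export
read_model_set <- function(path) {
  cfg <- yaml::read_yaml(path)
  models <- map(cfg$models, config_to_model)
  tree <- if (!is.null(cfg$tree)) {
    weight_tree(map(cfg$tree, function(b) {
      list(weight = b$weight, model_ids = unlist(b$model_ids),
           aics = unlist(b$aics))
    }))
  } else NULL
  model_set(cfg$id, cfg$cancer_group, models, tree = tree)
}

#' Read grouped cohort cells from delimited text
#'
#' @param path CSV with header columns s, a, e, d, c, ic, n, py.
#' @return A [cohort_cells()] tibble.
#' @export
read_cohort_cells <- function(path) {
  cohort_cells(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write cohort cells to delimited text
#'
#' @param cells A [cohort_cells()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_cells <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' Write a population table to delimited text
#'
#' @param table A [population_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
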