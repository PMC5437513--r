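# Readers and writers: tracer dataset CSV, protocol/run configuration
# YAML, fit-result JSON.  One unit convention everywhere on disk:
# concentrations molar, time days, volumes litres, tracer observables as
# fraction of injected dose.

#' Read a tracer dataset from CSV
#'
#' Schema: `time_days,pool,fraction_of_dose[,sd]`.  Pool names are
#' normalized (case/whitespace; a few common synonyms accepted) to the
#' fixed vocabulary `plasma, duodenum, bone_marrow, rbc, liver, spleen,
#' rest, excreted`; schema violations report the offending row.  The
#' `sd` column is optional: without it the dataset fits unweighted.
#'
#' @param path CSV file path.
#' @return a `tracer_data` data.frame.
#' @export
read_tracer_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_days", "pool", "fraction_of_dose")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("'", path, "': missing column(s): ", paste(miss, collapse = ", "))
  d$pool <- .normalize_pool(d$pool)
  if (!"sd" %in% names(d)) d$sd <- NA_real_
  validate_tracer_data(d, where = paste0("'", path, "'"))
  structure(d[, c("time_days", "pool", "fraction_of_dose", "sd")],
            class = c("tracer_data", "data.frame"))
}

.normalize_pool <- function(x) {
  key <- gsub("[ .-]+", "_", tolower(trimws(x)))
  syn <- c(bone_marrow = "bone_marrow", bonemarrow = "bone_marrow",
           bm = "bone_marrow", marrow = "bone_marrow",
           rbc = "rbc", red_blood_cells = "rbc", erythrocytes = "rbc",
           rest = "rest", rest_of_body = "rest",
           excreted = "excreted", outside = "excreted",
           plasma = "plasma", duodenum = "duodenum", liver = "liver",
           spleen = "spleen")
  out <- unname(syn[key])
  ifelse(is.na(out), x, out)
}

#' @rdname read_tracer_csv
#' @param dataset a `tracer_data`.
#' @export
write_tracer_csv <- function(dataset, path) {
  validate_tracer_data(dataset)
  d <- as.data.frame(dataset)
  if (all(is.na(d$sd))) d$sd <- NULL
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

.protocol_fields <- c("leadin_days", "injection_dose", "observation_times",
                      "diet_vDiet", "diet_kHepSyn", "horizon_days")

#' Read a simulation protocol from YAML
#'
#' Recognized fields: `leadin_days` (default 5000 de-novo, 35 for diet
#' switches), `injection_dose` (mol), `observation_times` (days),
#' `diet_vDiet` and `diet_kHepSyn` (M/day), `horizon_days`.  Unknown keys
#' are rejected rather than silently ignored.
#'
#' @param path YAML file.
#' @return named list of protocol settings.
#' @export
read_protocol_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.list(x)) stop("protocol YAML must be a mapping")
  bad <- setdiff(names(x), .protocol_fields)
  if (length(bad))
    stop("unknown protocol field(s): ", paste(bad, collapse = ", "))
  if (!is.null(x$leadin_days) && x$leadin_days < 0)
    stop("leadin_days must be >= 0")
  if (!is.null(x$injection_dose) && x$injection_dose < 0)
    stop("injection_dose must be >= 0")
  x
}

#' Read a complete run configuration from YAML
#'
#' Top-level keys: `seed`, `output_dir`, `params` (inline mapping, path
#' to a parameter JSON, or `fixture_column` 1..10), `protocol` (inline
#' protocol mapping), `fit` (free parameter names, SRES budget fields
#' `lambda`, `mu`, `generations`, `pf`, constraint window).  All
#' randomness downstream flows from the single `seed`.
#'
#' @param path YAML file.
#' @return list with validated `params` (`iron_params`), `protocol`,
#'   `fit`, `seed`, `output_dir`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  allowed <- c("seed", "output_dir", "params", "protocol", "fit")
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  p <- x$params
  params <- if (is.null(p)) iron_params()
  else if (is.character(p)) read_params_json(p)
  else if (!is.null(p$fixture_column)) published_params(p$fixture_column)
  else do.call(iron_params, as.list(unlist(p)))
  protocol <- if (is.null(x$protocol)) list() else {
    bad <- setdiff(names(x$protocol), .protocol_fields)
    if (length(bad))
      stop("unknown protocol field(s): ", paste(bad, collapse = ", "))
    x$protocol
  }
  list(seed = x$seed %||% 1L, output_dir = x$output_dir %||% ".",
       params = params, protocol = protocol, fit = x$fit %||% list())
}

#' Write a fit result as JSON with provenance
#'
#' @param fit an `iron_fit`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "iron_fit"))
  x <- list(
    params = as.list(unclass(fit$params)),
    sum_squares = fit$value,
    feasible = fit$feasible,
    total_iron_mg = fit$total_iron_mg,
    tf_saturation_pct = fit$tf_saturation_pct,
    rbc_transition_days = fit$rbc_transition_days,
    optimizer = fit$optimizer, seed = fit$seed, evals = fit$evals
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
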