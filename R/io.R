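## Long-format estimates schema shared by every stage.

MEASURE_VOCAB <- c("mx", "deaths", "prevalence", "yld_rate", "yll", "yld",
                   "daly", "sdi", "haq", "exposure", "paf", "sev", "hale",
                   "le", "pyih", "q_window", "arc", "attrib_daly",
                   "expected", "oe_ratio")

EST_KEY <- c("location_id", "year", "sex", "age_group_start", "cause",
             "measure")

validate_estimates <- function(dt) {
  req <- c("location_id", "year", "sex", "age_group_start", "age_group_end",
           "cause", "measure", "value")
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!dt$measure %in% MEASURE_VOCAB)
  if (length(bad)) {
    stop(sprintf("unknown measure '%s' at row %d", dt$measure[bad[1]], bad[1]),
         call. = FALSE)
  }
  dup <- which(duplicated(dt, by = EST_KEY))
  if (length(dup)) {
    stop(sprintf("duplicate key tuple at row %d (location %s, year %s, sex %s, age %s, cause %s, measure %s)",
                 dup[1], dt$location_id[dup[1]], dt$year[dup[1]],
                 dt$sex[dup[1]], dt$age_group_start[dup[1]],
                 dt$cause[dup[1]], dt$measure[dup[1]]), call. = FALSE)
  }
  invisible(dt)
}

#' Read a long-format estimates table
#'
#' Reads a UTF-8 CSV with the columns `location_id`, `year`, `sex`,
#' `age_group_start`, `age_group_end`, `cause`, `measure`, `value` (plus
#' optional `draw_*` columns), validates the closed measure vocabulary and
#' rejects duplicate key tuples.
#'
#' @param path Path to a CSV file.
#' @return A validated `data.table`.
#' @export
read_estimates <- function(path) {
  dt <- data.table::fread(path, encoding = "UTF-8")
  validate_estimates(dt)
  dt
}

#' Write a long-format estimates table
#'
#' Validates and writes the table so that `read_estimates(path)` is an
#' exact round trip.
#'
#' @param table Estimates table (coerced to `data.table`).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_estimates <- function(table, path) {
  dt <- data.table::as.data.table(table)
  validate_estimates(dt)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Maps a YAML document's top-level keys to [sim_config()] arguments;
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$disability_params)) {
    raw$disability_params <- as.data.frame(raw$disability_params)
  }
  if (!is.null(raw$sex_multiplier)) {
    raw$sex_multiplier <- unlist(raw$sex_multiplier)
  }
  do.call(sim_config, raw)
}

#' Read categorical risk specifications from YAML
#'
#' Expects a mapping of risk name to `prevalence` / `rr` /
#' (optional) `tmrel_index` entries.
#'
#' @param path YAML file path.
#' @return Named list of [risk_spec()] objects.
#' @export
read_risk_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    risk_spec(unlist(r$prevalence), unlist(r$rr),
              tmrel_index = r$tmrel_index)
  })
}
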