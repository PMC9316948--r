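#' Data-availability coverage matrix
#'
#' A long-format binary indicator of whether any input data exist for each
#' (country, cause-or-risk, period, age-restriction) cell. The age
#' restriction distinguishes sources covering all ages from sources
#' covering the population aged 70 and over only.
#'
#' @param df Data frame with columns `country`, `entity`, `entity_type`
#'   (`"cause"` or `"risk"`), `period`, `age_flag` (`"all_ages"` or
#'   `"aged_70_plus"`), `has_data` (0/1).
#' @return The validated data frame with class `coverage_matrix`.
#' @export
coverage_matrix <- function(df) {
  req <- c("country", "entity", "entity_type", "period", "age_flag", "has_data")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing coverage columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$has_data %in% c(0, 1))) {
    stop("`has_data` cells must be 0 or 1", call. = FALSE)
  }
  if (nrow(df) == 0) stop("coverage matrix is empty", call. = FALSE)
  structure(as.data.frame(df), class = c("coverage_matrix", "data.frame"))
}

# entities/countries absent from a slice have no data there: DCI 0
full_axis <- function(pct, axis) {
  out <- setNames(numeric(length(axis)), sort(as.character(axis)))
  out[names(pct)] <- pct
  out
}

cov_slice <- function(m, period, age_flag) {
  s <- m[m$period == period & m$age_flag == age_flag, , drop = FALSE]
  if (nrow(s) == 0) {
    stop(sprintf("no coverage cells for period '%s' and age flag '%s'",
                 period, age_flag), call. = FALSE)
  }
  s
}

#' Data coverage index by cause or risk
#'
#' For each cause/risk in the slice: the percentage of countries with at
#' least one input-data indicator.
#'
#' @param m A [coverage_matrix()].
#' @param period Period label to slice on.
#' @param age_flag `"all_ages"` or `"aged_70_plus"`.
#' @return Named numeric vector of percentages in `[0, 100]`, one per
#'   entity. The denominator is the full country axis of `m`.
#' @export
dci_by_cause <- function(m, period, age_flag = "all_ages") {
  stopifnot(inherits(m, "coverage_matrix"))
  s <- cov_slice(m, period, age_flag)
  n_countries <- length(unique(m$country))
  hit <- tapply(s$has_data, list(s$entity, s$country), max, default = 0)
  pct <- 100 * rowSums(hit > 0) / n_countries
  full_axis(pct, unique(m$entity))
}

#' Data coverage index by country
#'
#' For each country in the slice: the percentage of causes/risks with at
#' least one input-data indicator.
#'
#' @inheritParams dci_by_cause
#' @return Named numeric vector of percentages, one per country; the
#'   denominator is the full entity axis of `m`.
#' @export
dci_by_country <- function(m, period, age_flag = "all_ages") {
  stopifnot(inherits(m, "coverage_matrix"))
  s <- cov_slice(m, period, age_flag)
  n_entities <- length(unique(m$entity))
  hit <- tapply(s$has_data, list(s$country, s$entity), max, default = 0)
  pct <- 100 * rowSums(hit > 0) / n_entities
  full_axis(pct, unique(m$country))
}

#' Coverage gap between all-ages and 70-plus data
#'
#' Elementwise difference `DCI(all ages) - DCI(aged 70+)` for the same
#' period. A positive gap means data covering older adults are scarcer
#' than data covering the whole population.
#'
#' @param m A [coverage_matrix()].
#' @param period Period label.
#' @param by `"cause"` (gap per cause/risk) or `"country"`.
#' @return Named numeric vector of percentage-point gaps.
#' @export
dci_gap <- function(m, period, by = c("cause", "country")) {
  by <- match.arg(by)
  f <- if (by == "cause") dci_by_cause else dci_by_country
  for (flag in c("all_ages", "aged_70_plus")) {
    if (!any(m$period == period & m$age_flag == flag)) {
      stop(sprintf("age flag '%s' missing for period '%s'", flag, period),
           call. = FALSE)
    }
  }
  all_ages <- f(m, period, "all_ages")
  older <- f(m, period, "aged_70_plus")
  keys <- sort(union(names(all_ages), names(older)))
  fill <- function(v) ifelse(keys %in% names(v), v[keys], 0)
  setNames(fill(all_ages) - fill(older), keys)
}
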