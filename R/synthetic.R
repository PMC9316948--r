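#' Configuration for the synthetic estimate generator
#'
#' Defines a small synthetic world with the statistical shape of a
#' burden-of-disease results table: Gompertz all-cause mortality rising
#' with age, a handful of level-2-like causes splitting it via Dirichlet
#' fractions, age-increasing disability prevalence per cause, categorical
#' risk exposures with known relative risks, and a development covariate
#' (SDI) linked to mortality through a stored, invertible monotone curve.
#' Every stochastic element is seeded per stream (see [child_seed()]), so
#' adding a stratum never perturbs the draws of another and identical
#' configurations yield bit-identical output.
#'
#' The all-cause rate in age group starting at `a`, for location `l`, sex
#' `s`, year `t` is
#' `gompertz_alpha * exp(gompertz_beta * a) * sdi_multiplier(SDI_l) *
#'  sex_multiplier_s * exp(all_cause_trend * (t - min(years)))`,
#' and cause-specific rates are (time-tilted, renormalised) Dirichlet
#' fractions of it, so cause closure holds exactly.
#'
#' @param n_locations Number of synthetic locations.
#' @param years Calendar years to generate.
#' @param age_starts Start ages of the abridged grid; last group open.
#' @param causes Cause labels.
#' @param gompertz_alpha Baseline hazard at age 0 (per person-year).
#' @param gompertz_beta Log-hazard slope per year of age.
#' @param cause_dirichlet Dirichlet concentration per cause.
#' @param cause_trend Per-cause annual log tilt of the cause fractions
#'   (renormalised, so closure is preserved).
#' @param all_cause_trend Annual log change of the all-cause level.
#' @param sex_multiplier Named multipliers for sexes `"1"` (male) and
#'   `"2"` (female).
#' @param disability_params Data frame with columns `cause`, `intercept`,
#'   `slope` (prevalence = `intercept + slope * age`, clamped to `[0,1]`)
#'   and `dw` (disability weight in `[0,1]`).
#' @param risk_params Named list of risks, each a list with `prevalence`
#'   (simplex) and `rr` (relative risks, TMREL first with rr 1).
#' @param exposure_trend Annual improvement rate of risk exposure: each
#'   category's prevalence is tilted by `exp(-trend * years * (rr - 1))`
#'   and renormalised, so mass drifts toward the TMREL over time.
#' @param sdi_link_lambda Slope of the monotone SDI-to-mortality link
#'   `multiplier(sdi) = exp(lambda * (0.5 - sdi))`.
#' @param sdi_range Range the 1990 SDI values are drawn from.
#' @param sdi_annual_gain Deterministic annual SDI increment.
#' @param seed Integer root seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_locations = 20,
                       years = c(1990, 2005, 2019),
                       age_starts = seq(0, 95, by = 5),
                       causes = c("cardio_like", "cancer_like",
                                  "neuro_like", "injury_like"),
                       gompertz_alpha = 4e-5,
                       gompertz_beta = 0.09,
                       cause_dirichlet = c(4, 3, 2, 1),
                       cause_trend = c(-0.012, 0.004, 0.006, -0.004),
                       all_cause_trend = -0.008,
                       sex_multiplier = c(`1` = 1.12, `2` = 0.89),
                       disability_params = NULL,
                       risk_params = NULL,
                       exposure_trend = 0.02,
                       sdi_link_lambda = 1.2,
                       sdi_range = c(0.2, 0.9),
                       sdi_annual_gain = 0.004,
                       seed = 1L) {
  if (!is.numeric(gompertz_alpha) || gompertz_alpha <= 0) {
    stop("`gompertz_alpha` must be positive", call. = FALSE)
  }
  if (!is.numeric(gompertz_beta) || gompertz_beta < 0) {
    stop("`gompertz_beta` must be non-negative", call. = FALSE)
  }
  check_age_grid(age_starts)
  k <- length(causes)
  stopifnot(length(cause_dirichlet) == k, all(cause_dirichlet > 0),
            length(cause_trend) == k)
  if (is.null(disability_params)) {
    disability_params <- data.frame(
      cause = causes,
      intercept = c(0.00, 0.00, -0.15, 0.02)[seq_len(k)],
      slope = c(0.0060, 0.0015, 0.0050, 0.0020)[seq_len(k)],
      dw = c(0.10, 0.25, 0.35, 0.15)[seq_len(k)]
    )
  }
  stop_if_not_prob(disability_params$dw, "disability weight")
  if (is.null(risk_params)) {
    risk_params <- list(
      pressure_like = list(prevalence = c(0.40, 0.40, 0.20),
                           rr = c(1, 1.5, 2.5)),
      smoke_like = list(prevalence = c(0.60, 0.25, 0.15),
                        rr = c(1, 1.8, 3.0))
    )
  }
  structure(list(n_locations = as.integer(n_locations), years = years,
                 age_starts = age_starts, causes = causes,
                 gompertz_alpha = gompertz_alpha,
                 gompertz_beta = gompertz_beta,
                 cause_dirichlet = cause_dirichlet,
                 cause_trend = cause_trend,
                 all_cause_trend = all_cause_trend,
                 sex_multiplier = sex_multiplier,
                 disability_params = disability_params,
                 risk_params = risk_params,
                 exposure_trend = exposure_trend,
                 sdi_link_lambda = sdi_link_lambda,
                 sdi_range = sdi_range,
                 sdi_annual_gain = sdi_annual_gain,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' SDI-to-mortality multiplier and its inverse
#'
#' The stored monotone link used by the generator:
#' `multiplier(sdi) = exp(lambda * (0.5 - sdi))`, decreasing in SDI
#' (development lowers mortality) and exactly invertible, so
#' transition-curve recovery is testable against ground truth.
#'
#' @param sdi SDI values in `[0, 1]`.
#' @param lambda Link slope.
#' @return `sdi_multiplier()`: the mortality multiplier;
#'   `sdi_from_multiplier()`: the SDI that produces a given multiplier.
#' @export
sdi_multiplier <- function(sdi, lambda = 1.2) exp(lambda * (0.5 - sdi))

#' @rdname sdi_multiplier
#' @param multiplier Mortality multiplier(s).
#' @export
sdi_from_multiplier <- function(multiplier, lambda = 1.2) {
  0.5 - log(multiplier) / lambda
}

#' Generate per-location-year SDI and HAQ covariates
#'
#' SDI is drawn uniformly per location within `sdi_range` for the first
#' configured year and rises deterministically by `sdi_annual_gain` per
#' year (clamped to `[0, 1]`). HAQ is a noisy monotone transform of SDI
#' scaled to `[0, 100]`.
#'
#' @param config A [sim_config()].
#' @return `data.table` with columns `location_id`, `year`, `sdi`, `haq`.
#' @export
generate_sdi_haq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "sdi"))
  base <- runif(config$n_locations, config$sdi_range[1], config$sdi_range[2])
  haq_noise <- rnorm(config$n_locations, 0, 2)
  out <- data.table::CJ(location_id = seq_len(config$n_locations),
                        year = config$years)
  y0 <- min(config$years)
  out[, `:=`(
    sdi = pmin(pmax(base[location_id] +
                      config$sdi_annual_gain * (year - y0), 0), 1))]
  out[, haq := pmin(pmax(100 * sdi^1.2 + haq_noise[location_id], 0), 100)]
  out[]
}

dirichlet_fractions <- function(alpha, seed) {
  set.seed(seed)
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate cause- and age-specific mortality estimates
#'
#' Produces a long-format estimates table (measure `"mx"`) for every
#' (location, sex, year) stratum. See [sim_config()] for the generative
#' model. Cause fractions are drawn once per (location, sex) from a
#' Dirichlet and tilted over time by `cause_trend` with renormalisation,
#' so the cause-specific rates always sum exactly to the all-cause rate.
#'
#' @param config A [sim_config()].
#' @param sdi_haq Optional covariate table from [generate_sdi_haq()]
#'   (regenerated from `config` if omitted).
#' @return `data.table` in the long estimates schema.
#' @export
generate_mortality <- function(config, sdi_haq = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sdi_haq)) sdi_haq <- generate_sdi_haq(config)
  ages <- config$age_starts
  k <- length(config$causes)
  y0 <- min(config$years)
  age_end <- c(ages[-1], NA_real_)

  rows <- vector("list", config$n_locations * 2L * length(config$years))
  idx <- 0L
  for (loc in seq_len(config$n_locations)) {
    for (sex in c(1L, 2L)) {
      base_frac <- dirichlet_fractions(config$cause_dirichlet,
                                       child_seed(config$seed, "frac", loc, sex))
      for (yr in config$years) {
        sdi <- sdi_haq[location_id == loc & year == yr, sdi]
        mult <- sdi_multiplier(sdi, config$sdi_link_lambda) *
          config$sex_multiplier[[as.character(sex)]] *
          exp(config$all_cause_trend * (yr - y0))
        all_cause <- config$gompertz_alpha * exp(config$gompertz_beta * ages) * mult
        frac <- base_frac * exp(config$cause_trend * (yr - y0))
        frac <- frac / sum(frac)
        idx <- idx + 1L
        rows[[idx]] <- data.table::data.table(
          location_id = loc, year = yr, sex = sex,
          age_group_start = rep(ages, each = k),
          age_group_end = rep(age_end, each = k),
          cause = rep(config$causes, length(ages)),
          measure = "mx",
          value = as.vector(t(outer(all_cause, frac)))
        )
      }
    }
  }
  data.table::rbindlist(rows)
}

#' Generate sequela prevalences and unadjusted YLD rates
#'
#' Per-cause prevalence follows the linear-in-age model
#' `intercept + slope * age`, clamped to `[0, 1]`; the unadjusted YLD rate
#' is `prevalence * disability_weight`. Both are emitted as measures
#' `"prevalence"` and `"yld_rate"` on the mortality table's strata.
#'
#' @param config A [sim_config()].
#' @param mortality Estimates table from [generate_mortality()] (defines
#'   the strata to populate).
#' @return `data.table` in the long estimates schema.
#' @export
generate_ylds <- function(config, mortality) {
  stopifnot(inherits(config, "sim_config"))
  dp <- config$disability_params
  stop_if_not_prob(dp$dw, "disability weight")
  strata <- unique(mortality[, .(location_id, year, sex)])
  ages <- config$age_starts
  age_end <- c(ages[-1], NA_real_)
  per_stratum <- data.table::rbindlist(lapply(seq_len(nrow(dp)), function(i) {
    prev <- pmin(pmax(dp$intercept[i] + dp$slope[i] * ages, 0), 1)
    data.table::data.table(
      age_group_start = rep(ages, 2L), age_group_end = rep(age_end, 2L),
      cause = dp$cause[i],
      measure = rep(c("prevalence", "yld_rate"), each = length(ages)),
      value = c(prev, prev * dp$dw[i])
    )
  }))
  out <- data.table::rbindlist(lapply(seq_len(nrow(strata)), function(i) {
    cbind(strata[i], per_stratum)
  }))
  out[]
}

#' Generate a synthetic data-coverage matrix
#'
#' Independent Bernoulli(1 - sparsity) has-data indicators over every
#' (country, entity, period, age flag) cell, seeded from the
#' configuration's root seed.
#'
#' @param config A [sim_config()].
#' @param sparsity Probability that a cell has no data, in `[0, 1]`.
#' @param periods Period labels.
#' @return A [coverage_matrix()].
#' @export
generate_coverage <- function(config, sparsity = 0.3,
                              periods = c("1990-2005", "2005-2019")) {
  stopifnot(inherits(config, "sim_config"))
  stop_if_not_prob(sparsity, "sparsity")
  entities <- c(config$causes, names(config$risk_params))
  grid <- expand.grid(
    country = paste0("location_", seq_len(config$n_locations)),
    entity = entities,
    entity_type = NA_character_,
    period = periods,
    age_flag = c("all_ages", "aged_70_plus"),
    stringsAsFactors = FALSE
  )
  grid$entity_type <- ifelse(grid$entity %in% config$causes, "cause", "risk")
  set.seed(child_seed(config$seed, "coverage"))
  grid$has_data <- as.integer(runif(nrow(grid)) >= sparsity)
  coverage_matrix(grid)
}

#' Extract a mortality surface for one stratum from an estimates table
#'
#' @param est Long estimates table containing `measure == "mx"` rows.
#' @param location,sex_code,yr Stratum selectors.
#' @return A [mortality_surface()].
#' @export
surface_from_estimates <- function(est, location, sex_code, yr) {
  est <- data.table::as.data.table(est)
  s <- est[measure == "mx" & location_id == location &
             sex == sex_code & year == yr]
  if (nrow(s) == 0) stop("no mx rows for the requested stratum", call. = FALSE)
  wide <- data.table::dcast(s, age_group_start ~ cause, value.var = "value")
  data.table::setorder(wide, age_group_start)
  mortality_surface(wide$age_group_start,
                    as.matrix(wide[, -1, with = FALSE]))
}
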