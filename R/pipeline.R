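#' Bundled synthetic standard life-expectancy table
#'
#' Remaining "standard" life expectancy per age group, used as the
#' reference for years-of-life-lost computations. This is a synthetic
#' stand-in built from a low-mortality Gompertz schedule (it is not any
#' official reference standard); supply your own table for real analyses.
#'
#' @param path Optional CSV with columns `age_start`, `std_le`; defaults
#'   to the bundled synthetic standard.
#' @return `data.frame` with columns `age_start`, `std_le`.
#' @export
standard_life_expectancy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "standard_le_synthetic.csv",
                        package = "ageburden")
  }
  out <- utils::read.csv(path)
  stopifnot(all(c("age_start", "std_le") %in% names(out)))
  out
}

adjusted_yld_by_age <- function(prev_mat, dw, mode = "analytic") {
  # prev_mat: ages x causes; returns list(total=vector, per_cause=matrix)
  k <- ncol(prev_mat)
  per_cause <- matrix(0, nrow(prev_mat), k, dimnames = dimnames(prev_mat))
  for (a in seq_len(nrow(prev_mat))) {
    adj <- comorbidity_adjust(prev_mat[a, ], dw, mode = mode)
    per_cause[a, ] <- adj
  }
  list(total = rowSums(per_cause), per_cause = per_cause)
}

#' Healthspan metrics for every stratum of an estimates table
#'
#' For each (location, sex, year) stratum: builds the abridged life table
#' from the all-cause mortality rates (sum over causes), derives
#' comorbidity-adjusted per-capita YLD rates from the sequela prevalences
#' and disability weights (recovered as `yld_rate / prevalence`), and
#' computes LE-70, HALE-70 (Sullivan), PYIH-70 and 20q70.
#'
#' @param est Long estimates table with measures `mx`, `prevalence` and
#'   `yld_rate`.
#' @param at_age Start age for the reported metrics (default 70).
#' @param window Width of the death-probability window (default 20).
#' @param ax_rule Passed to [build_lifetable()].
#' @return `data.table` with one row per stratum: `location_id`, `year`,
#'   `sex`, `le`, `hale`, `pyih`, `q_window`.
#' @export
compute_healthspan <- function(est, at_age = 70, window = 20,
                               ax_rule = "midpoint") {
  est <- data.table::as.data.table(est)
  strata <- unique(est[measure == "mx", .(location_id, year, sex)])
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    loc <- strata$location_id[i]; yr <- strata$year[i]; sx <- strata$sex[i]
    surf <- surface_from_estimates(est, loc, sx, yr)
    all_cause <- rowSums(surf$mx)
    lt <- build_lifetable(surf$age_start, all_cause, ax_rule = ax_rule)

    pr <- data.table::dcast(
      est[measure == "prevalence" & location_id == loc &
            sex == sx & year == yr],
      age_group_start ~ cause, value.var = "value")
    data.table::setorder(pr, age_group_start)
    yr_rate <- data.table::dcast(
      est[measure == "yld_rate" & location_id == loc &
            sex == sx & year == yr],
      age_group_start ~ cause, value.var = "value")
    data.table::setorder(yr_rate, age_group_start)
    prev_mat <- as.matrix(pr[, -1, with = FALSE])
    yld_mat <- as.matrix(yr_rate[, -1, with = FALSE])
    dw <- vapply(seq_len(ncol(prev_mat)), function(j) {
      pos <- prev_mat[, j] > 0
      if (!any(pos)) return(0)
      stats::median(yld_mat[pos, j] / prev_mat[pos, j])
    }, numeric(1))

    adj <- adjusted_yld_by_age(prev_mat, dw)
    hale_all <- hale_sullivan(lt, adj$total)
    le <- life_expectancy_at(lt, at_age)
    hale <- unname(hale_all[as.character(at_age)])
    out[[i]] <- data.table::data.table(
      location_id = loc, year = yr, sex = sx,
      le = le, hale = hale, pyih = pyih(le, hale),
      q_window = prob_death_window(lt, at_age, window))
  }
  data.table::rbindlist(out)
}

tilt_prevalence <- function(prevalence, rr, trend, years_elapsed) {
  p <- prevalence * exp(-trend * years_elapsed * (rr - 1))
  p / sum(p)
}

#' Risk-factor summaries for a synthetic scenario
#'
#' Computes, per risk and year, the exposure-tilted PAF and SEV, the
#' attributable share of the 70-plus DALY rate, and the annualised rate of
#' change of SEV between the first and last configured years.
#'
#' @param config A [sim_config()].
#' @param healthspan Output of [compute_healthspan()] (used only for
#'   reporting keys; attributable burden is computed against `daly_rate`).
#' @param daly_rate Optional per-year all-cause 70-plus DALY rate table
#'   (`year`, `value`); if omitted, PAFs are reported without attribution.
#' @return `data.table` with columns `risk`, `year`, `measure`, `value`.
#' @export
compute_risk_summaries <- function(config, healthspan = NULL,
                                   daly_rate = NULL) {
  stopifnot(inherits(config, "sim_config"))
  y0 <- min(config$years)
  rows <- list()
  for (risk in names(config$risk_params)) {
    rp <- config$risk_params[[risk]]
    sev_by_year <- numeric(0)
    for (yr in config$years) {
      p <- tilt_prevalence(rp$prevalence, rp$rr, config$exposure_trend, yr - y0)
      spec <- risk_spec(p, rp$rr)
      paf_v <- paf(spec)
      sev_v <- sev(spec)
      sev_by_year[as.character(yr)] <- sev_v
      rows[[length(rows) + 1L]] <- data.table::data.table(
        risk = risk, year = yr,
        measure = c("paf", "sev"), value = c(paf_v, sev_v))
      if (!is.null(daly_rate)) {
        b <- daly_rate$value[daly_rate$year == yr]
        if (length(b) == 1) {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            risk = risk, year = yr, measure = "attrib_daly",
            value = attributable_burden(paf_v, b))
        }
      }
    }
    n_years <- diff(range(config$years))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      risk = risk, year = max(config$years), measure = "arc",
      value = annualized_rate_of_change(sev_by_year[as.character(y0)],
                                        sev_by_year[as.character(max(config$years))],
                                        n_years))
  }
  data.table::rbindlist(rows)
}

log_stage <- function(lines, stage, n_in, n_out, seed) {
  line <- sprintf("stage=%s rows_in=%d rows_out=%d seed=%d",
                  stage, n_in, n_out, seed)
  message(line)
  c(lines, line)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates every stage end to end on a synthetic scenario: covariate
#' and estimate generation, per-stratum life tables and healthspan metrics
#' (LE-70, HALE-70, PYIH-70, 20q70), cause decomposition of the change in
#' 20q70 between the first and last years, risk summaries (PAF, SEV,
#' attributable DALY rate, annualised rate of change), the
#' epidemiological-transition fit of LE-70 against SDI with
#' observed-to-expected ratios, and data-coverage indices. Deterministic
#' given the configuration seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, every table is written
#'   as CSV along with a `summary_log.txt`.
#' @param decompose_strata How many (location, sex) strata to decompose
#'   (kept small by default; each decomposition enumerates orderings).
#' @return Invisibly, a named list of result tables.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         decompose_strata = 6L) {
  stopifnot(inherits(config, "sim_config"))
  lines <- character(0)

  sdi_haq <- generate_sdi_haq(config)
  lines <- log_stage(lines, "covariates", 0L, nrow(sdi_haq), config$seed)

  mort <- generate_mortality(config, sdi_haq)
  lines <- log_stage(lines, "mortality", nrow(sdi_haq), nrow(mort), config$seed)

  ylds <- generate_ylds(config, mort)
  est <- data.table::rbindlist(list(mort, ylds))
  lines <- log_stage(lines, "ylds", nrow(mort), nrow(est), config$seed)

  hs <- compute_healthspan(est)
  lines <- log_stage(lines, "healthspan", nrow(est), nrow(hs), config$seed)

  # decomposition of the 20q70 change, first vs last year
  y1 <- min(config$years); y2 <- max(config$years)
  strata <- unique(mort[, .(location_id, sex)])
  strata <- head(strata, decompose_strata)
  dec <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    s1 <- surface_from_estimates(mort, strata$location_id[i], strata$sex[i], y1)
    s2 <- surface_from_estimates(mort, strata$location_id[i], strata$sex[i], y2)
    d <- decompose_20q70(s1, s2)
    dec[[i]] <- data.table::data.table(
      location_id = strata$location_id[i], sex = strata$sex[i],
      cause = names(d$contributions),
      contribution = unname(d$contributions),
      share_of_change = unname(d$contributions) / d$total_change,
      total_change = d$total_change)
  }
  dec <- data.table::rbindlist(dec)
  lines <- log_stage(lines, "decomposition", nrow(mort), nrow(dec), config$seed)

  # per-year global 70+ DALY rate (per capita, life-table weighted)
  std <- standard_life_expectancy()
  daly_rate <- daly_rate_70plus(est, std)
  risks <- compute_risk_summaries(config, hs, daly_rate)
  lines <- log_stage(lines, "risks", nrow(hs), nrow(risks), config$seed)

  hs_cov <- merge(hs, sdi_haq, by = c("location_id", "year"))
  tm <- fit_expected_curve(hs_cov$sdi, hs_cov$le, covariate = "sdi")
  hs_cov[, expected := predict(tm, sdi)]
  hs_cov[, oe_ratio := observed_expected_ratio(le, tm, sdi)]
  lines <- log_stage(lines, "transition", nrow(hs), nrow(hs_cov), config$seed)

  cov <- generate_coverage(config)
  periods <- unique(cov$period)
  dci_cause <- data.table::rbindlist(lapply(periods, function(p) {
    v <- dci_by_cause(cov, p, "aged_70_plus")
    data.table::data.table(period = p, entity = names(v), dci = unname(v))
  }))
  dci_country <- data.table::rbindlist(lapply(periods, function(p) {
    v <- dci_by_country(cov, p, "aged_70_plus")
    data.table::data.table(period = p, country = names(v), dci = unname(v))
  }))
  dci_gap_tab <- data.table::rbindlist(lapply(periods, function(p) {
    v <- dci_gap(cov, p, by = "cause")
    data.table::data.table(period = p, entity = names(v), gap = unname(v))
  }))
  lines <- log_stage(lines, "coverage", nrow(cov), nrow(dci_cause), config$seed)

  results <- list(estimates = est, sdi_haq = sdi_haq, healthspan = hs,
                  decomposition = dec, risks = risks, transition = hs_cov,
                  transition_model = tm, coverage = cov,
                  dci_by_cause = dci_cause, dci_by_country = dci_country,
                  dci_gap = dci_gap_tab, log = lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_estimates(est, file.path(out_dir, "estimates.csv"))
    for (nm in c("sdi_haq", "healthspan", "decomposition", "risks",
                 "transition", "dci_by_cause", "dci_by_country", "dci_gap")) {
      data.table::fwrite(results[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    jsonlite::write_json(
      list(covariate = tm$covariate, knots = tm$knots, boundary = tm$boundary,
           coefficients = unname(tm$coefficients), offset = tm$offset),
      file.path(out_dir, "transition_model.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(lines, file.path(out_dir, "summary_log.txt"))
  }
  invisible(results)
}

#' Per-capita all-cause DALY rate above age 70
#'
#' Life-table-weighted rate: for each year,
#' `sum_{a >= 70} L_a (sum_c mx_c(a) std_le(a) + yld_c(a)) / T_70`,
#' averaged over strata. Used as the outcome burden for risk attribution
#' in the synthetic pipeline.
#'
#' @param est Long estimates table with `mx` and `yld_rate` measures.
#' @param std Standard life-expectancy table (`age_start`, `std_le`).
#' @return `data.table` with columns `year`, `value`.
#' @export
daly_rate_70plus <- function(est, std = standard_life_expectancy()) {
  est <- data.table::as.data.table(est)
  strata <- unique(est[measure == "mx", .(location_id, year, sex)])
  vals <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    loc <- strata$location_id[i]; yr <- strata$year[i]; sx <- strata$sex[i]
    surf <- surface_from_estimates(est, loc, sx, yr)
    lt <- build_lifetable(surf$age_start, rowSums(surf$mx))
    yld <- data.table::dcast(
      est[measure == "yld_rate" & location_id == loc &
            sex == sx & year == yr],
      age_group_start ~ cause, value.var = "value")
    data.table::setorder(yld, age_group_start)
    std_le <- std$std_le[match(surf$age_start, std$age_start)]
    keep <- surf$age_start >= 70
    rate_a <- rowSums(surf$mx) * std_le + rowSums(as.matrix(yld[, -1, with = FALSE]))
    w <- lt$Lx[keep]
    vals[[i]] <- data.table::data.table(
      year = yr, value = sum(w * rate_a[keep]) / sum(w))
  }
  data.table::rbindlist(vals)[, .(value = mean(value)), by = year]
}
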