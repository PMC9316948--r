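#' Categorical risk-exposure specification
#'
#' Describes one risk-outcome pair with categorical exposure: per-category
#' exposure prevalences (a probability simplex), per-category relative
#' risks, and the index of the theoretical minimum risk exposure level
#' (TMREL), whose relative risk must equal 1.
#'
#' @param prevalence Per-category exposure fractions summing to 1.
#' @param rr Per-category relative risks, all positive.
#' @param tmrel_index Index of the TMREL category (default: the first
#'   category with `rr == 1`).
#' @param categories Optional category labels.
#' @return An object of class `risk_spec`.
#' @export
risk_spec <- function(prevalence, rr, tmrel_index = NULL, categories = NULL) {
  stopifnot(length(prevalence) == length(rr))
  if (any(!is.finite(prevalence)) || any(prevalence < 0) ||
      abs(sum(prevalence) - 1) > 1e-9) {
    stop("`prevalence` must be a probability simplex (non-negative, summing to 1)",
         call. = FALSE)
  }
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("relative risks must be positive and finite", call. = FALSE)
  }
  if (is.null(tmrel_index)) tmrel_index <- which(rr == 1)[1]
  if (is.na(tmrel_index) || rr[tmrel_index] != 1) {
    stop("the TMREL category must have relative risk exactly 1", call. = FALSE)
  }
  if (is.null(categories)) categories <- paste0("cat_", seq_along(rr))
  structure(list(categories = categories, prevalence = prevalence, rr = rr,
                 tmrel_index = as.integer(tmrel_index)),
            class = "risk_spec")
}

#' Population attributable fraction for a categorical risk
#'
#' The proportional reduction in outcome burden if the whole population
#' were shifted to the TMREL category:
#' `PAF = (sum(p * rr) - 1) / sum(p * rr)`.
#'
#' @param spec A [risk_spec()].
#' @return A fraction in `(-Inf, 1)`; non-negative whenever all `rr >= 1`.
#' @examples
#' paf(risk_spec(c(0.5, 0.5), c(1, 2)))  # 1/3
#' @export
paf <- function(spec) {
  stopifnot(inherits(spec, "risk_spec"))
  m <- sum(spec$prevalence * spec$rr)
  (m - 1) / m
}

#' Attributable burden
#'
#' Multiplies a population attributable fraction by the outcome burden
#' (e.g. DALYs) to obtain the burden attributable to the risk.
#'
#' @param paf_value Attributable fraction(s).
#' @param outcome_burden Non-negative burden in person-years.
#' @return Attributable person-years, additive across outcomes.
#' @export
attributable_burden <- function(paf_value, outcome_burden) {
  if (any(outcome_burden < 0)) stop("burden must be non-negative", call. = FALSE)
  paf_value * outcome_burden
}

#' Summary exposure value
#'
#' A risk-weighted exposure prevalence scaled to `[0, 1]`:
#' `SEV = sum(p * (rr - 1)) / (max(rr) - 1)`. It equals 0 when all
#' exposure sits at the TMREL and 1 when all exposure sits at the
#' maximum-risk category; undefined for a null risk (all `rr == 1`).
#'
#' @param spec A [risk_spec()].
#' @return SEV in `[0, 1]` for specs with `rr >= 1`.
#' @examples
#' sev(risk_spec(c(0.5, 0.5), c(1, 3)))  # 0.5
#' @export
sev <- function(spec) {
  stopifnot(inherits(spec, "risk_spec"))
  rr_max <- max(spec$rr)
  if (rr_max == 1) stop("SEV undefined for null risk (all relative risks equal 1)",
                        call. = FALSE)
  sum(spec$prevalence * (spec$rr - 1)) / (rr_max - 1)
}

#' Annualised rate of change
#'
#' The constant per-year log rate that carries `initial` to `final` over
#' `n_years`: `log(final / initial) / n_years`.
#'
#' @param initial,final Positive values of the quantity at the two ends.
#' @param n_years Positive number of years between them.
#' @return Per-year log rate; positive when the quantity increased.
#' @examples
#' annualized_rate_of_change(1, 2, 29)  # log(2)/29
#' @export
annualized_rate_of_change <- function(initial, final, n_years) {
  for (nm in c("initial", "final", "n_years")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be positive and finite", nm), call. = FALSE)
    }
  }
  log(final / initial) / n_years
}
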