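#' Comorbidity-adjusted YLD rates
#'
#' Combines per-sequela prevalences and disability weights into per-sequela
#' years-lived-with-disability (YLD) rates per capita, adjusting for
#' comorbidity under independence. A person carrying the set `S` of
#' conditions has combined disability `1 - prod_{i in S} (1 - dw_i)`
#' (multiplicative aggregation), which is attributed back to the
#' co-occurring conditions proportionally to their individual weights.
#'
#' `mode = "analytic"` enumerates all `2^k` co-occurrence sets exactly and
#' is limited to 20 conditions; `mode = "microsim"` draws `n_sim`
#' individuals with independent Bernoulli condition indicators and
#' converges to the analytic answer at the Monte-Carlo rate.
#'
#' @param prevalence Per-condition prevalences in `[0, 1]`.
#' @param dw Per-condition disability weights in `[0, 1]`.
#' @param mode `"analytic"` (exact enumeration) or `"microsim"`.
#' @param n_sim Number of simulated individuals for `"microsim"`.
#' @param seed Integer seed for `"microsim"`.
#' @return Numeric vector of adjusted per-condition YLD rates per capita
#'   (named after `prevalence` if it has names), with attribute `"combined"`
#'   holding the total expected disability per person. In `"microsim"`
#'   mode, attributes `"se"` and `"combined_se"` carry the Monte-Carlo
#'   standard errors.
#' @examples
#' # two certain conditions: combined 1 - 0.8*0.7 = 0.44,
#' # split 0.176 / 0.264 by weight
#' comorbidity_adjust(c(1, 1), c(0.2, 0.3))
#' @export
comorbidity_adjust <- function(prevalence, dw,
                               mode = c("analytic", "microsim"),
                               n_sim = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(prevalence) == length(dw), length(prevalence) >= 1)
  stop_if_not_prob(prevalence, "prevalence")
  stop_if_not_prob(dw, "dw")
  k <- length(prevalence)

  if (mode == "analytic") {
    if (k > 20) {
      stop("analytic enumeration supports at most 20 conditions; use mode = \"microsim\"",
           call. = FALSE)
    }
    attrib <- numeric(k)
    combined <- 0
    for (code in seq_len(2^k) - 1L) {
      in_set <- bitwAnd(code, 2L^(seq_len(k) - 1L)) > 0L
      p_set <- prod(ifelse(in_set, prevalence, 1 - prevalence))
      if (p_set == 0 || !any(in_set)) next
      dw_set <- 1 - prod(1 - dw[in_set])
      combined <- combined + p_set * dw_set
      denom <- sum(dw[in_set])
      if (denom > 0) {
        attrib[in_set] <- attrib[in_set] + p_set * dw_set * dw[in_set] / denom
      }
    }
  } else {
    set.seed(seed)
    has <- matrix(runif(n_sim * k) < rep(prevalence, each = n_sim), n_sim, k)
    one_minus <- matrix(rep(1 - dw, each = n_sim), n_sim, k)
    one_minus[!has] <- 1
    dw_person <- 1 - apply(one_minus, 1L, prod)
    w <- matrix(rep(dw, each = n_sim), n_sim, k)
    w[!has] <- 0
    denom <- rowSums(w)
    share <- w / ifelse(denom > 0, denom, 1)
    contrib <- share * dw_person
    attrib <- colMeans(contrib)
    combined <- mean(dw_person)
    se <- apply(contrib, 2L, sd) / sqrt(n_sim)
    names(attrib) <- names(prevalence)
    return(structure(attrib, combined = combined, se = se,
                     combined_se = sd(dw_person) / sqrt(n_sim)))
  }
  names(attrib) <- names(prevalence)
  structure(attrib, combined = combined)
}

#' Years of life lost
#'
#' YLLs are deaths multiplied by the remaining standard life expectancy at
#' the age of death, summed per cause and age group.
#'
#' @param deaths Matrix or data.frame of death counts, rows = age groups,
#'   columns = causes; non-negative.
#' @param standard_le Remaining standard life expectancy per age group, on
#'   the same grid (same number of rows).
#' @return Matrix of YLLs with the same shape as `deaths`.
#' @export
yll <- function(deaths, standard_le) {
  deaths <- as.matrix(deaths)
  if (any(deaths < 0)) stop("death counts must be non-negative", call. = FALSE)
  if (any(standard_le < 0)) stop("standard life expectancy must be non-negative", call. = FALSE)
  if (nrow(deaths) != length(standard_le)) {
    stop("`deaths` and `standard_le` are on different age grids", call. = FALSE)
  }
  deaths * standard_le
}

#' Sullivan-method healthy life expectancy
#'
#' Weights the life-table person-years of each age group by the fraction of
#' time lived in full health, `1 - yld_rate`, and accumulates from each age
#' upward: `HALE(x) = sum_{a >= x} L_a (1 - yld_a) / l_x`. With zero YLD
#' rates this reduces to ordinary life expectancy.
#'
#' @param lt A `lifetable`.
#' @param yld_rate Per-capita comorbidity-adjusted YLD rate per age group
#'   of `lt`, each in `[0, 1]`.
#' @return Numeric vector of HALE at every grid age (named by age).
#' @examples
#' lt <- build_lifetable(seq(0, 95, 5), rep(0.05, 20))
#' hale_sullivan(lt, rep(0.25, 20))[["70"]]  # 0.75 * LE-70
#' @export
hale_sullivan <- function(lt, yld_rate) {
  stopifnot(inherits(lt, "lifetable"))
  if (length(yld_rate) != nrow(lt)) {
    stop("`yld_rate` must match the life-table age grid", call. = FALSE)
  }
  stop_if_not_prob(yld_rate, "yld_rate")
  healthy_L <- lt$Lx * (1 - yld_rate)
  setNames(rev(cumsum(rev(healthy_L))) / lt$lx, lt$age_start)
}

#' Proportion of remaining years spent in ill health
#'
#' `PYIH = (LE - HALE) / LE` at the same start age: the expected fraction
#' of the years left that will be lived in less than full health.
#'
#' @param le70 Remaining life expectancy (years), positive.
#' @param hale70 Healthy life expectancy (years), in `[0, le70]`.
#' @return The ill-health fraction in `[0, 1]`. Rounding is left to the
#'   reporting layer (conventionally [round_half_up()] to 2 decimals).
#' @export
pyih <- function(le70, hale70) {
  if (any(le70 <= 0)) stop("`le70` must be positive", call. = FALSE)
  if (any(hale70 < 0) || any(hale70 > le70)) {
    stop("`hale70` must lie in [0, le70]", call. = FALSE)
  }
  (le70 - hale70) / le70
}

#' Disability-adjusted life years
#'
#' Cellwise `DALY = YLL + YLD` over aligned cause-by-age tables.
#'
#' @param yll_tab,yld_tab Non-negative matrices of identical shape.
#' @return Matrix of DALYs.
#' @export
daly <- function(yll_tab, yld_tab) {
  yll_tab <- as.matrix(yll_tab); yld_tab <- as.matrix(yld_tab)
  if (!identical(dim(yll_tab), dim(yld_tab))) {
    stop("YLL and YLD tables are on different grids", call. = FALSE)
  }
  if (any(yll_tab < 0) || any(yld_tab < 0)) {
    stop("burden tables must be non-negative", call. = FALSE)
  }
  yll_tab + yld_tab
}
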