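#' Build an abridged period life table
#'
#' Converts a schedule of age-specific all-cause mortality rates `mx`
#' (deaths per person-year) on an abridged age grid into the standard
#' life-table columns. The final age group is treated as open-ended and
#' closed with the constant-hazard rule `Lx = lx / mx` (so `ex = 1/mx`
#' there).
#'
#' Two within-interval assumptions are offered for closed intervals:
#' \describe{
#'   \item{`midpoint`}{deaths occur on average halfway through the
#'     interval, `ax = n/2`, with the usual conversion
#'     `qx = n*mx / (1 + (n - ax)*mx)`. This is the common abridged-table
#'     default for adult ages.}
#'   \item{`exponential`}{a piecewise-constant hazard within each interval,
#'     `qx = 1 - exp(-n*mx)` and `Lx = dx/mx`. Exact when the true hazard
#'     is constant, which makes closed-form checks (`ex = 1/mu`) hold to
#'     machine precision.}
#' }
#'
#' @param age_start Numeric vector of interval start ages (years), strictly
#'   increasing; the last interval is open-ended.
#' @param mx Positive mortality rates, one per age group.
#' @param ax_rule `"midpoint"` (default) or `"exponential"`.
#' @param radix Number of survivors at the first age (cosmetic only; all
#'   derived quantities are radix-invariant).
#' @return A `data.frame` of class `lifetable` with columns `age_start`,
#'   `n`, `mx`, `ax`, `qx`, `lx`, `dx`, `Lx`, `Tx`, `ex`.
#' @examples
#' lt <- build_lifetable(seq(0, 95, 5), rep(0.05, 20), ax_rule = "exponential")
#' life_expectancy_at(lt, 70)   # ~ 1 / 0.05 = 20
#' @seealso [life_expectancy_at()], [prob_death_window()]
#' @export
build_lifetable <- function(age_start, mx,
                            ax_rule = c("midpoint", "exponential"),
                            radix = 1e5) {
  ax_rule <- match.arg(ax_rule)
  check_age_grid(age_start)
  if (length(mx) != length(age_start)) {
    stop("`mx` must have one rate per age group", call. = FALSE)
  }
  bad <- which(!is.finite(mx) | mx <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive mortality rate in age group starting at %g",
                 age_start[bad[1]]), call. = FALSE)
  }
  k <- length(mx)
  n <- c(diff(age_start), Inf)

  qx <- numeric(k)
  ax <- numeric(k)
  closed <- seq_len(k - 1L)
  if (ax_rule == "midpoint") {
    ax[closed] <- n[closed] / 2
    qx[closed] <- n[closed] * mx[closed] /
      (1 + (n[closed] - ax[closed]) * mx[closed])
  } else {
    qx[closed] <- 1 - exp(-n[closed] * mx[closed])
  }
  qx[closed] <- pmin(qx[closed], 1)
  qx[k] <- 1
  ax[k] <- 1 / mx[k]

  lx <- radix * cumprod(c(1, 1 - qx[closed]))
  dx <- lx * qx

  Lx <- numeric(k)
  if (ax_rule == "midpoint") {
    Lx[closed] <- n[closed] * (lx[closed] - dx[closed]) + ax[closed] * dx[closed]
  } else {
    Lx[closed] <- dx[closed] / mx[closed]
    # implied average years lived by those dying in the interval
    ax[closed] <- ifelse(dx[closed] > 0,
                         (Lx[closed] - n[closed] * (lx[closed] - dx[closed])) /
                           dx[closed],
                         n[closed] / 2)
  }
  Lx[k] <- lx[k] / mx[k]

  Tx <- rev(cumsum(rev(Lx)))
  ex <- Tx / lx

  out <- data.frame(age_start = age_start, n = n, mx = mx, ax = ax, qx = qx,
                    lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
  class(out) <- c("lifetable", "data.frame")
  out
}

lt_row <- function(lt, age) {
  i <- match(age, lt$age_start)
  if (is.na(i)) {
    stop(sprintf("age %g is not on the life-table grid (no interpolation)", age),
         call. = FALSE)
  }
  i
}

#' Remaining life expectancy at a grid age
#'
#' @param lt A `lifetable` from [build_lifetable()].
#' @param age A start age present on the grid (e.g. 70 for LE-70).
#' @return Expected remaining years of life at that exact age.
#' @export
life_expectancy_at <- function(lt, age) {
  stopifnot(inherits(lt, "lifetable"))
  lt$ex[lt_row(lt, age)]
}

#' Probability of death within an age window
#'
#' The life-table probability of dying between exact ages `start` and
#' `start + span`, `1 - l(start+span) / l(start)`. With the defaults this
#' is 20q70, the probability of death between ages 70 and 90.
#'
#' @param lt A `lifetable`.
#' @param start Window start age (grid point), default 70.
#' @param span Window width in years, positive; `start + span` must also be
#'   a grid point, default 20.
#' @return A probability in `[0, 1]`.
#' @export
prob_death_window <- function(lt, start = 70, span = 20) {
  stopifnot(inherits(lt, "lifetable"))
  if (!is.numeric(span) || span <= 0) stop("`span` must be positive", call. = FALSE)
  i <- lt_row(lt, start)
  j <- lt_row(lt, start + span)
  1 - lt$lx[j] / lt$lx[i]
}
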