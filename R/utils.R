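#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of most
#' published summary tables), as opposed to the IEEE banker's rounding used
#' by [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.285, 2)  # 0.29, where round() gives 0.28
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so that values stored just under .5 round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Derive a reproducible child seed from a root seed and a stream label
#'
#' A documented counter scheme: each named stream gets its own seed derived
#' from the root, so adding one stratum never perturbs the draws of another.
#' The result always lies in `[0, 2^31 - 2]`.
#'
#' @param seed Integer root seed.
#' @param ... Stream labels (coerced to character and hashed).
#' @return A single integer seed.
#' @export
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

stop_if_not_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_age_grid <- function(age_start) {
  if (length(age_start) < 2L) stop("age grid needs at least two groups", call. = FALSE)
  if (is.unsorted(age_start, strictly = TRUE)) {
    stop("age grid must be strictly increasing", call. = FALSE)
  }
  invisible(age_start)
}
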