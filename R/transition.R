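#' Fit the expected-value curve of an ageing metric against a development
#' covariate
#'
#' Models the historical average relation between a non-negative metric
#' (e.g. LE-70, HALE-70, PYIH-70) and a development covariate (SDI or the
#' HAQ index) as an ordinary least-squares cubic regression spline with an
#' intercept, fitted in log space: `log(metric + offset) ~ bs(covariate)`.
#' Interior knots sit at equally spaced quantiles of the observed
#' covariate. The small additive offset keeps zeros finite in log space.
#'
#' @param covariate_values Covariate observations (one per location-year).
#' @param metric_values Non-negative metric observations, same length.
#' @param covariate Which covariate the values represent, `"sdi"` or
#'   `"haq"` (recorded in the model object).
#' @param n_knots Number of interior knots (default 4, at quantiles
#'   0.2/0.4/0.6/0.8).
#' @param offset Log-space offset, default `1e-7`.
#' @return An object of class `transition_model` holding the basis
#'   definition, coefficients, fitted range, and in-sample expected values.
#' @examples
#' x <- runif(500); y <- exp(1 + 0.8 * x)
#' m <- fit_expected_curve(x, y)
#' all.equal(predict(m, x), y, tolerance = 1e-4)
#' @export
fit_expected_curve <- function(covariate_values, metric_values,
                               covariate = c("sdi", "haq"),
                               n_knots = 4, offset = 1e-7) {
  covariate <- match.arg(covariate)
  x <- as.numeric(covariate_values)
  y <- as.numeric(metric_values)
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(y < 0)) {
    stop("observations must be finite and metric values non-negative", call. = FALSE)
  }
  n_par <- n_knots + 4L  # cubic basis + intercept
  if (length(x) < n_par) {
    stop(sprintf("need at least %d observations to fit %d parameters",
                 n_par, n_par), call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("covariate is degenerate (zero variance)", call. = FALSE)
  }
  knots <- unname(quantile(x, probs = seq_len(n_knots) / (n_knots + 1),
                           type = 7))
  boundary <- range(x)
  X <- cbind(1, splines::bs(x, knots = knots, degree = 3L,
                            Boundary.knots = boundary))
  ly <- log(y + offset)
  fit <- lm.fit(X, ly)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0  # aliased columns (duplicate covariate values)

  model <- structure(list(covariate = covariate, knots = knots,
                          boundary = boundary, coefficients = beta,
                          offset = offset,
                          log_residual_mean = mean(ly - X %*% beta)),
                     class = "transition_model")
  model$fitted <- predict(model, x)
  model
}

#' Predict expected metric values from a transition model
#'
#' @param object A `transition_model`.
#' @param newdata Covariate values at which to predict.
#' @param ... Unused.
#' @return Expected metric values on the natural scale (back-transformed
#'   from log space, offset removed, clamped at 0). Covariate values
#'   outside the fitted range trigger a warning and are extrapolated; the
#'   result then carries a logical attribute `"extrapolated"`.
#' @export
predict.transition_model <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  out_of_range <- x < object$boundary[1] | x > object$boundary[2]
  if (any(out_of_range)) {
    warning(sprintf("%d covariate value(s) outside the fitted range [%g, %g]; extrapolating",
                    sum(out_of_range), object$boundary[1], object$boundary[2]))
  }
  # bs() repeats its own warning for out-of-range values; ours (above) is
  # the documented contract
  X <- cbind(1, suppressWarnings(
    splines::bs(x, knots = object$knots, degree = 3L,
                Boundary.knots = object$boundary)))
  expected <- pmax(exp(drop(X %*% object$coefficients)) - object$offset, 0)
  if (any(out_of_range)) attr(expected, "extrapolated") <- out_of_range
  expected
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model: log-space cubic spline on %s, %d interior knots, offset %g>\n",
              toupper(x$covariate), length(x$knots), x$offset))
  invisible(x)
}

#' Observed-to-expected ratio
#'
#' Compares an observed metric value with the expected value from the
#' fitted transition curve at the same covariate value:
#' `ratio = (observed + offset) / (expected + offset)`. Ratios above 1 mean
#' the observed level exceeds the level expected for that stage of
#' development.
#'
#' @param observed Non-negative observed metric value(s).
#' @param model A fitted `transition_model`.
#' @param covariate_value Covariate value(s) at which each observation was
#'   made.
#' @return Ratio(s) on the natural scale.
#' @export
observed_expected_ratio <- function(observed, model, covariate_value) {
  stopifnot(inherits(model, "transition_model"))
  if (any(observed < 0)) stop("`observed` must be non-negative", call. = FALSE)
  expected <- predict(model, covariate_value)
  (observed + model$offset) / (as.numeric(expected) + model$offset)
}
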