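#' A dose-response series for one chemical-species pair
#'
#' @param concentration odorant dilutions, vol/vol fractions (> 0).
#' @param response responses in spikes/s (control-subtracted; may be
#'   negative).
#' @param chemical,species labels identifying the pair.
#' @param normalized set `TRUE` when responses are already on the
#'   percent-of-maximum scale (0-100) and must not be rescaled again.
#' @return object of class `dose_response_series`.
#' @export
dose_response_series <- function(concentration, response,
                                 chemical = "odorant", species = "sp",
                                 normalized = FALSE) {
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) == 0)
    stop("empty dose-response series")
  if (length(concentration) != length(response))
    stop("'concentration' and 'response' lengths differ")
  if (any(concentration <= 0))
    stop("concentrations must be strictly positive")
  structure(list(concentration = concentration, response = response,
                 chemical = chemical, species = species,
                 normalized = isTRUE(normalized)),
            class = "dose_response_series")
}

#' Normalize a series to its largest response
#'
#' Responses are floored at 0, then scaled so the largest response within
#' the chemical-species pair maps to 100 (percent of maximum), with the
#' minimum set to 0. Flooring applies only here; raw four-parameter fits
#' see the unfloored values.
#'
#' @param series a [dose_response_series()].
#' @return the normalized series (`$normalized` set to `TRUE`).
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "dose_response_series"))
  if (isTRUE(series$normalized)) return(series)
  mx <- max(series$response)
  if (!is.finite(mx) || mx <= 0)
    stop("normalization impossible: maximum response is <= 0")
  series$response <- pmax(series$response, 0) / mx * 100
  series$normalized <- TRUE
  series
}

## Logistic fitted in log10-concentration space for conditioning:
## y = d + (a - d) / (1 + 10^(h * (lec50 - log10 x))).
.logistic10 <- function(lx, lec50, h, a, d) d + (a - d) / (1 + 10^(h * (lec50 - lx)))

## Start values: ec50 at the concentration whose response is nearest
## half-max, restart grid over h in {0.5, 1, 2}. Returns the best
## converged nlsLM fit or NULL.
.fit_logistic <- function(lx, y, four_param) {
  a0 <- max(y); d0 <- min(y)
  lec50_0 <- lx[which.min(abs(y - (a0 + d0) / 2))]
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch({
      if (four_param)
        minpack.lm::nlsLM(y ~ .logistic10(lx, lec50, h, a, d),
                          data = data.frame(lx = lx, y = y),
                          start = list(lec50 = lec50_0, h = h0, a = a0, d = d0),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ .logistic10(lx, lec50, h, a = 100, d = 0),
                          data = data.frame(lx = lx, y = y),
                          start = list(lec50 = lec50_0, h = h0),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < attr(best, "rss")) {
        attr(fit, "rss") <- rss
        best <- fit
      }
    }
  }
  best
}

.ec50_result <- function(series, method, ec50 = NA_real_, hill = NA_real_,
                         ymin = NA_real_, ymax = NA_real_, converged = FALSE,
                         residual_norm = NA_real_, fallback_value = NA_real_) {
  structure(list(chemical = series$chemical, species = series$species,
                 ec50 = ec50, method = method, hill = hill,
                 min = ymin, max = ymax, converged = converged,
                 residual_norm = residual_norm,
                 fallback_value = fallback_value,
                 series = series),
            class = "ec50_fit")
}

## "failed to fit": optimizer non-convergence, non-positive Hill slope,
## or an EC50 outside [min conc, max conc * 100]. An EC50 below the
## lowest tested concentration means the whole transition was
## unobserved (the "calculated value of 0" failure); above the range a
## factor of 100 is allowed because a non-saturating top still brackets
## the midpoint usefully.
.fit_ok <- function(res) {
  rng <- range(res$series$concentration)
  res$converged && is.finite(res$ec50) && res$hill > 0 &&
    res$ec50 >= rng[1] && res$ec50 <= rng[2] * 100
}

#' Two-parameter logistic EC50 fit on a normalized series
#'
#' Least-squares fit of `y = 100 / (1 + (ec50/x)^h)` over `(ec50, h)`,
#' with the plateau fixed at 100% and the floor at 0 (as set by
#' [normalize_series()]). Non-convergence is reported in the result, not
#' raised.
#'
#' @param series a normalized [dose_response_series()].
#' @return an object of class `ec50_fit`.
#' @export
fit_two_param <- function(series) {
  stopifnot(inherits(series, "dose_response_series"))
  if (!isTRUE(series$normalized))
    stop("fit_two_param expects a normalized series; see normalize_series()")
  if (length(unique(series$concentration)) < 3)
    stop("need >= 3 distinct concentrations to fit")
  fit <- .fit_logistic(log10(series$concentration), series$response,
                       four_param = FALSE)
  if (is.null(fit))
    return(.ec50_result(series, "two_param_normalized"))
  cf <- stats::coef(fit)
  .ec50_result(series, "two_param_normalized",
               ec50 = 10^cf[["lec50"]], hill = cf[["h"]],
               ymin = 0, ymax = 100, converged = TRUE,
               residual_norm = sqrt(attr(fit, "rss")))
}

#' Four-parameter logistic EC50 fit on a raw series
#'
#' Fit of `y = d + (a - d) / (1 + (ec50/x)^h)` with the maximum and
#' minimum responses as free parameters; used when the two-parameter
#' normalized fit fails or when the top concentration does not reach
#' saturation. Responses are not floored.
#'
#' @param series a raw (unnormalized) [dose_response_series()].
#' @return an object of class `ec50_fit`.
#' @export
fit_four_param <- function(series) {
  stopifnot(inherits(series, "dose_response_series"))
  if (length(unique(series$concentration)) < 3)
    stop("need >= 3 distinct concentrations to fit")
  fit <- .fit_logistic(log10(series$concentration), series$response,
                       four_param = TRUE)
  if (is.null(fit))
    return(.ec50_result(series, "four_param"))
  cf <- stats::coef(fit)
  .ec50_result(series, "four_param",
               ec50 = 10^cf[["lec50"]], hill = cf[["h"]],
               ymin = cf[["d"]], ymax = cf[["a"]], converged = TRUE,
               residual_norm = sqrt(attr(fit, "rss")))
}

#' Estimate an EC50 under the two-parameter / four-parameter / fallback
#' policy
#'
#' The primary route is the two-parameter fit on the normalized series
#' (plateau 100, floor 0). The four-parameter raw fit is used when the
#' two-parameter fit fails, when normalization is impossible (no positive
#' response), or for chemicals on the forced list - odorants such as
#' SBITC whose highest tested concentration does not reach saturation,
#' where a fixed plateau of 100% would be wrong. When both fits fail
#' (non-convergence, non-positive slope, or an EC50 collapsing outside
#' the tested range, i.e. a degenerate value of ~0), the minimum observed
#' response within the chemical-species group is recorded instead and the
#' method is flagged `min_value_fallback`.
#'
#' @param series a raw [dose_response_series()].
#' @param force_four_param character vector of chemical names that must
#'   take the four-parameter route regardless of two-parameter success.
#' @return an `ec50_fit` whose `$method` is one of
#'   `"two_param_normalized"`, `"four_param"`, `"min_value_fallback"`.
#' @export
estimate_ec50 <- function(series, force_four_param = character(0)) {
  stopifnot(inherits(series, "dose_response_series"))
  if (length(series$concentration) == 0) stop("empty series")
  forced <- series$chemical %in% force_four_param

  if (!forced) {
    res2 <- tryCatch(fit_two_param(normalize_series(series)),
                     error = function(e) NULL)
    if (!is.null(res2) && .fit_ok(res2)) {
      res2$series <- series
      return(res2)
    }
  }
  res4 <- fit_four_param(series)
  if (.fit_ok(res4)) return(res4)

  .ec50_result(series, "min_value_fallback",
               ec50 = min(series$response),
               fallback_value = min(series$response))
}

#' @export
print.ec50_fit <- function(x, ...) {
  cat(sprintf("EC50 fit: %s / %s\n", x$chemical, x$species))
  cat(sprintf("  method: %s  converged: %s\n", x$method, x$converged))
  if (x$method == "min_value_fallback")
    cat(sprintf("  fallback value (min observed response): %.4g\n",
                x$fallback_value))
  else
    cat(sprintf("  EC50: %.4g vol/vol  hill: %.3g  range: [%.3g, %.3g]\n",
                x$ec50, x$hill, x$min, x$max))
  invisible(x)
}

#' @export
coef.ec50_fit <- function(object, ...) {
  c(ec50 = object$ec50, hill = object$hill,
    min = object$min, max = object$max)
}

#' @export
predict.ec50_fit <- function(object, newdata = NULL, ...) {
  if (object$method == "min_value_fallback")
    stop("no fitted curve for a min_value_fallback result")
  x <- if (is.null(newdata)) object$series$concentration
       else if (is.list(newdata)) newdata$concentration else newdata
  .logistic10(log10(x), log10(object$ec50), object$hill,
              object$max, object$min)
}

#' @export
residuals.ec50_fit <- function(object, ...) {
  y <- object$series$response
  if (object$method == "two_param_normalized")
    y <- normalize_series(object$series)$response
  y - predict(object)
}
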