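# Biochemical model fits: single-exponential single-turnover glycosylase
# time courses, tangent-method lag times from growth curves, and
# four-parameter Hill IC50 fits for lag-time and percent-survival
# dose-response data.
#
# Models:
#   time course      P(t)   = A * (1 - exp(-k * t))
#   lag dose-resp.   lag(c) = min + (max - min) / (1 + (IC50 / c)^h)
#   survival         S(c)   = min + (max - min) / (1 + (c / IC50)^h)
# All fits are bounded least squares (Levenberg-Marquardt) with a
# deterministic log-spaced multistart; objective tolerance 1e-10.

.nls_control <- function() minpack.lm::nls.lm.control(
  ftol = 1e-10, ptol = 1e-10, maxiter = 500)

#' Validate a kinetic time course
#'
#' Times must be strictly increasing; fractions are expected in [0, 1]
#' (small excursions, as from noisy gel quantification, draw a warning, not
#' an error).
#'
#' @param time minutes, strictly increasing.
#' @param fraction_product fraction of substrate converted.
#' @return `data.frame` with columns `time`, `fraction_product`.
#' @export
time_course <- function(time, fraction_product) {
  stopifnot(length(time) == length(fraction_product))
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(fraction_product < -0.1 | fraction_product > 1.1))
    stop("fractions far outside [0, 1]")
  if (any(fraction_product < 0 | fraction_product > 1))
    warning("fraction_product outside [0, 1]; keeping values as measured")
  data.frame(time = as.numeric(time),
             fraction_product = as.numeric(fraction_product))
}

#' Fit a single-exponential glycosylase time course
#'
#' Least-squares fit of `P(t) = A (1 - exp(-k t))` with `k >= 0` and
#' `0 <= A <= 1.05` (no offset: the assay measures fraction product from
#' zero). When the reaction is already complete at the earliest time point
#' the rate is reported as a lower bound (`k_lower_bound = TRUE`); an
#' all-zero trace yields `A ~ 0` with `k` flagged unidentifiable.
#'
#' @param tc a [time_course()] `data.frame` (>= 3 points), or `time` when
#'   `fraction_product` is given.
#' @param fraction_product optional numeric vector (with `tc` the times).
#' @return an object of class `exp_fit` with components `k` (min^-1),
#'   `amplitude`, `rss`, `k_lower_bound`, `k_unidentifiable`, `fitted`,
#'   `data`. Methods: `print`, `coef`, `predict`, `residuals`, `summary`.
#' @export
fit_single_exponential <- function(tc, fraction_product = NULL) {
  if (!is.null(fraction_product)) tc <- time_course(tc, fraction_product)
  stopifnot(nrow(tc) >= 3L)
  t <- tc$time; y <- tc$fraction_product
  if (max(abs(y)) < 1e-8) {
    fit <- structure(list(k = NA_real_, amplitude = 0, rss = sum(y^2),
                          k_lower_bound = FALSE, k_unidentifiable = TRUE,
                          fitted = rep(0, length(y)), data = tc),
                     class = "exp_fit")
    return(fit)
  }
  a0 <- min(max(y), 1.05)
  # deterministic multistart: log-spaced k plus an initial-slope heuristic
  k_slope <- if (t[1] > 0 && y[1] > 0 && y[1] < a0) {
    -log(1 - y[1] / a0) / t[1]
  } else NA_real_
  k_grid <- unique(c(10^seq(-2, 2, length.out = 5),
                     if (is.finite(k_slope) && k_slope > 0) k_slope))
  best <- NULL
  for (k0 in k_grid) {
    f <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ A * (1 - exp(-k * t)), start = list(A = a0, k = k0),
      lower = c(A = 0, k = 0), upper = c(A = 1.05, k = Inf),
      control = .nls_control())), silent = TRUE)
    if (inherits(f, "try-error")) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = f, rss = rss)
  }
  if (is.null(best))
    stop("single-exponential fit failed to converge from any start")
  cf <- stats::coef(best$fit)
  plateau <- y[1] >= 0.95 * cf[["A"]] && cf[["A"]] > 0
  structure(list(k = cf[["k"]], amplitude = cf[["A"]], rss = best$rss,
                 k_lower_bound = plateau, k_unidentifiable = FALSE,
                 fitted = stats::fitted(best$fit), data = tc,
                 nls = best$fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("Single-exponential fit: P(t) = A (1 - exp(-k t))\n")
  cat(sprintf("  k = %s min^-1%s\n",
              format(x$k, digits = 4),
              if (isTRUE(x$k_lower_bound))
                " (lower bound: complete at earliest time point)" else ""))
  if (isTRUE(x$k_unidentifiable)) cat("  k unidentifiable (flat trace)\n")
  cat(sprintf("  A = %s, RSS = %.3g on %d points\n",
              format(x$amplitude, digits = 4), x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) c(k = object$k, A = object$amplitude)

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else
    if (is.data.frame(newdata)) newdata$time else newdata
  object$amplitude * (1 - exp(-object$k * t))
}

#' @export
residuals.exp_fit <- function(object, ...)
  object$data$fraction_product - object$fitted

#' @export
summary.exp_fit <- function(object, ...) {
  se <- tryCatch(sqrt(diag(stats::vcov(object$nls))),
                 error = function(e) c(A = NA_real_, k = NA_real_))
  out <- list(coefficients = cbind(Estimate = coef(object),
                                   `Std. Error` = c(se[["k"]], se[["A"]])),
              rss = object$rss, k_lower_bound = object$k_lower_bound)
  class(out) <- "summary.exp_fit"
  out
}

#' @export
print.summary.exp_fit <- function(x, ...) {
  print(x$coefficients); invisible(x)
}

#' Estimate lag time from a growth curve
#'
#' Geometric (tangent) lag: the intersection of the steepest log-linear
#' tangent of the growth curve with the baseline optical density.
#' Deterministic for fixed input. A curve that never exceeds twice its
#' baseline is reported as no growth, with the maximal lag (last time point)
#' as sentinel.
#'
#' @param time hours, strictly increasing (>= 5 points).
#' @param od OD600 readings, positive.
#' @return list with `lag` (h), `no_growth` flag, `slope` (max log-OD slope,
#'   per h) and `t_max_slope`.
#' @export
estimate_lag_time <- function(time, od) {
  stopifnot(length(time) == length(od), length(time) >= 5L, all(od > 0))
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  baseline <- min(od[seq_len(3)])
  if (max(od) < 2 * baseline)
    return(list(lag = max(time), no_growth = TRUE, slope = NA_real_,
                t_max_slope = NA_real_))
  l <- log(od)
  slopes <- diff(l) / diff(time)            # slope on [i, i+1]
  i <- which.max(slopes)
  slope <- slopes[i]
  t_star <- time[i]                          # segment start anchors the tangent
  lag <- t_star - (l[i] - log(baseline)) / slope
  list(lag = max(lag, 0), no_growth = FALSE, slope = slope,
       t_max_slope = t_star)
}

.hill_response <- function(dose, minr, maxr, ic50, h, direction) {
  ratio <- if (direction == "increasing") (ic50 / dose)^h else (dose / ic50)^h
  ratio[dose == 0] <- if (direction == "increasing") Inf else 0
  minr + (maxr - minr) / (1 + ratio)
}

.fit_hill <- function(dose, response, direction) {
  stopifnot(length(dose) == length(response), length(dose) >= 4L,
            all(dose >= 0))
  if (any(diff(dose) <= 0)) stop("doses must be strictly increasing")
  if (stats::sd(response) < 1e-8 * max(1, abs(mean(response))))
    return(structure(list(ic50 = NA_real_, hill = NA_real_,
                          min_response = mean(response),
                          max_response = mean(response),
                          rss = sum((response - mean(response))^2),
                          no_inhibition = TRUE, direction = direction,
                          fitted = rep(mean(response), length(dose)),
                          data = data.frame(dose = dose, response = response)),
                     class = "ic50_fit"))
  pos <- dose[dose > 0]
  ic_grid <- exp(seq(log(min(pos)), log(max(pos)), length.out = 5))
  min0 <- min(response); max0 <- max(response)
  best <- NULL
  for (ic0 in ic_grid) {
    f <- try(suppressWarnings(minpack.lm::nlsLM(
      response ~ .hill_response(dose, minr, maxr, ic50, h, direction),
      start = list(minr = min0, maxr = max0, ic50 = ic0, h = 1),
      lower = c(minr = -Inf, maxr = -Inf, ic50 = 1e-12, h = 1e-6),
      control = .nls_control())), silent = TRUE)
    if (inherits(f, "try-error")) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = f, rss = rss)
  }
  if (is.null(best))
    stop("IC50 fit failed to converge from any start; check dose coverage")
  cf <- stats::coef(best$fit)
  structure(list(ic50 = cf[["ic50"]], hill = cf[["h"]],
                 min_response = cf[["minr"]], max_response = cf[["maxr"]],
                 rss = best$rss, no_inhibition = FALSE, direction = direction,
                 fitted = stats::fitted(best$fit),
                 data = data.frame(dose = dose, response = response),
                 nls = best$fit),
            class = "ic50_fit")
}

#' Fit the lag-time Hill equation
#'
#' Least-squares fit of
#' `lag = min_lag + (max_lag - min_lag) / (1 + (IC50/dose)^h)` (response
#' increasing with dose; at `dose = 0` the predicted lag is `min_lag`, at
#' `dose = IC50` exactly the midpoint of min and max).
#'
#' @param dose doses (uM), strictly increasing, including 0 and a saturating
#'   dose; >= 4 points.
#' @param response lag times (h).
#' @return an object of class `ic50_fit` (`ic50`, `hill`, `min_response`,
#'   `max_response`, `rss`, flags). Methods: `print`, `coef`, `predict`,
#'   `residuals`.
#' @export
fit_ic50_lag <- function(dose, response) .fit_hill(dose, response, "increasing")

#' Fit the percent-survival Hill equation
#'
#' Same four-parameter Hill form with response decreasing in dose (maximum at
#' dose 0); IC50 is the dose of half-maximal survival. A constant ~100%
#' response is flagged `no_inhibition`.
#'
#' @param dose doses (uM), strictly increasing; >= 4 points.
#' @param response percent survival.
#' @return an `ic50_fit` object.
#' @export
fit_ic50_survival <- function(dose, response)
  .fit_hill(dose, response, "decreasing")

#' @export
print.ic50_fit <- function(x, ...) {
  cat("Hill dose-response fit (", x$direction, " response)\n", sep = "")
  if (isTRUE(x$no_inhibition)) {
    cat("  no inhibition detected (flat response)\n")
  } else {
    cat(sprintf("  IC50 = %s, Hill slope = %s\n", format(x$ic50, digits = 4),
                format(x$hill, digits = 3)))
    cat(sprintf("  response range [%s, %s], RSS = %.3g\n",
                format(x$min_response, digits = 4),
                format(x$max_response, digits = 4), x$rss))
  }
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...)
  c(ic50 = object$ic50, h = object$hill, min_response = object$min_response,
    max_response = object$max_response)

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose else
    if (is.data.frame(newdata)) newdata$dose else newdata
  if (isTRUE(object$no_inhibition)) return(rep(object$min_response, length(d)))
  .hill_response(d, object$min_response, object$max_response, object$ic50,
                 object$hill, object$direction)
}

#' @export
residuals.ic50_fit <- function(object, ...)
  object$data$response - object$fitted

#' Percent survival from colony counts
#'
#' `100 * CFU/mL(treated) / CFU/mL(untreated)`.
#'
#' @param cfu_treated,cfu_untreated colony-forming units per mL;
#'   `cfu_untreated > 0`.
#' @return percent survival.
#' @export
percent_survival <- function(cfu_treated, cfu_untreated) {
  if (any(cfu_untreated <= 0)) stop("untreated CFU/mL must be positive")
  100 * cfu_treated / cfu_untreated
}

#' Fold change between two IC50 values
#'
#' @param ic50_a,ic50_b positive IC50 values (same units).
#' @return `ic50_a / ic50_b`.
#' @export
fold_change <- function(ic50_a, ic50_b) {
  if (any(c(ic50_a, ic50_b) <= 0)) stop("IC50 values must be positive")
  ic50_a / ic50_b
}
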