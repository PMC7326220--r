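#' Size-dependent performance model of secondary structure prediction
#'
#' Bundles the fitted relationships between PSSM target-dataset size
#' `n_t` (number of proteins searched by PSI-BLAST) and the average
#' performance of state-of-the-art SSP methods:
#' \describe{
#'   \item{time cost}{`TC(n_t) = tc_slope * n_t + tc_intercept` seconds —
#'     PSSM generation dominates and scales linearly with the database.}
#'   \item{Q3}{a generalized (asymmetric) logistic in `log2(n_t)`:
#'     `amplitude / (1 + exp((midpoint - log2(n_t))/scale))^asymmetry +
#'     baseline`.}
#'   \item{Q8}{a plain logistic in `log2(n_t)` (asymmetry fixed at 1).}
#' }
#' The default coefficients are the reference fit obtained on random
#' size-reduction series of UniRef90 (halving series down from tens of
#' millions of proteins, seven SSP methods averaged, TS115 query set).
#' Time-cost constants are hardware-bound: they predict relative, not
#' absolute, runtimes on other machines (see the fitted object's
#' `hardware_note`).
#'
#' @param tc_slope,tc_intercept linear time-cost coefficients
#'   (seconds per target protein; seconds).
#' @param q3 named numeric vector with elements `amplitude`, `midpoint`,
#'   `scale`, `asymmetry`, `baseline`.
#' @param q8 named numeric vector with elements `amplitude`, `midpoint`,
#'   `scale`, `baseline`.
#' @return An object of class `size_perf_model`.
#' @examples
#' m <- size_perf_model()
#' predict(m, quantity = "Q3", n_t = 87.3e6)
#' @export
size_perf_model <- function(tc_slope = 2.8658e-5, tc_intercept = 5.8248,
                            q3 = c(amplitude = 0.1363, midpoint = 17.0963,
                                   scale = 2.1447, asymmetry = 0.6205,
                                   baseline = 0.6716),
                            q8 = c(amplitude = 0.1281, midpoint = 15.6095,
                                   scale = 2.5405, baseline = 0.5621)) {
  stopifnot(tc_slope > 0,
            all(c("amplitude", "midpoint", "scale", "asymmetry",
                  "baseline") %in% names(q3)),
            all(c("amplitude", "midpoint", "scale", "baseline") %in%
                  names(q8)),
            q3[["scale"]] > 0, q8[["scale"]] > 0)
  structure(list(tc_slope = tc_slope, tc_intercept = tc_intercept,
                 q3 = q3, q8 = q8,
                 hardware_note = paste("time-cost constants are specific",
                                       "to the hardware they were fitted",
                                       "on; use for relative comparisons")),
            class = "size_perf_model")
}

#' Homology-dependent performance model
#'
#' Polynomial fits describing SSP performance when the target dataset's
#' sequence redundancy is reduced (and its size shrinks passively):
#' time cost is quadratic in the dataset size `n_t`, while Q3 and Q8 are
#' cubic in the identity cutoff `c_t` (percent; a `c_t`% non-redundant
#' set has no pair above `c_t`% mutual identity). Coefficients are given
#' highest degree first, as printed by `polyroot`-style conventions.
#'
#' @param tc quadratic coefficients over `n_t` (degree 2, 1, 0).
#' @param q3,q8 cubic coefficients over `c_t` (degree 3, 2, 1, 0).
#' @return An object of class `homology_perf_model`.
#' @examples
#' m <- homology_perf_model()
#' predict(m, quantity = "Q3", c_t = 100)
#' @export
homology_perf_model <- function(tc = c(-4.0386e-14, 3.2338e-05, -73.9573),
                                q3 = c(-1.0552e-7, 1.4931e-5, -0.0006,
                                       0.8152),
                                q8 = c(-9.3552e-8, 1.5515e-5, -0.0008,
                                       0.7000)) {
  stopifnot(length(tc) == 3L, length(q3) == 4L, length(q8) == 4L,
            all(is.finite(c(tc, q3, q8))))
  structure(list(tc = tc, q3 = q3, q8 = q8,
                 hardware_note = paste("time-cost constants are specific",
                                       "to the hardware they were fitted",
                                       "on; use for relative comparisons")),
            class = "homology_perf_model")
}

# descending-degree polynomial evaluation
polyval <- function(coefs, x) {
  y <- 0
  for (c_i in coefs) y <- y * x + c_i
  y
}

gen_logistic <- function(p, log2n) {
  asym <- if ("asymmetry" %in% names(p)) p[["asymmetry"]] else 1
  p[["amplitude"]] /
    (1 + exp((p[["midpoint"]] - log2n) / p[["scale"]]))^asym +
    p[["baseline"]]
}

#' @describeIn size_perf_model Predict time cost or accuracy at target
#'   dataset size `n_t` (proteins). `quantity` is one of `"TC"`, `"Q3"`,
#'   `"Q8"`.
#' @param object a `size_perf_model`.
#' @param quantity which fitted curve to evaluate.
#' @param n_t target-dataset size(s), >= 1.
#' @param ... unused.
#' @export
predict.size_perf_model <- function(object, quantity = c("TC", "Q3", "Q8"),
                                    n_t, ...) {
  quantity <- match.arg(quantity)
  if (any(n_t < 1)) stop("'n_t' must be >= 1")
  switch(quantity,
         TC = object$tc_slope * n_t + object$tc_intercept,
         Q3 = gen_logistic(object$q3, log2(n_t)),
         Q8 = gen_logistic(object$q8, log2(n_t)))
}

#' @describeIn homology_perf_model Predict at dataset size `n_t`
#'   (for `"TC"`) or identity cutoff `c_t` in percent (for `"Q3"`/`"Q8"`).
#'   Inputs outside the fitted range (`c_t` in \[20,100\], `n_t >= 1`)
#'   are still evaluated but flagged with a warning as extrapolation.
#' @param object a `homology_perf_model`.
#' @param quantity which fitted curve to evaluate.
#' @param n_t dataset size(s) for the time-cost quadratic.
#' @param c_t identity cutoff(s) in percent for the accuracy cubics.
#' @param ... unused.
#' @export
predict.homology_perf_model <- function(object,
                                        quantity = c("TC", "Q3", "Q8"),
                                        n_t = NULL, c_t = NULL, ...) {
  quantity <- match.arg(quantity)
  if (quantity == "TC") {
    if (is.null(n_t)) stop("'n_t' required for TC")
    if (any(n_t < 1))
      warning("n_t below the fitted range; extrapolating")
    polyval(object$tc, n_t)
  } else {
    if (is.null(c_t)) stop("'c_t' required for ", quantity)
    if (any(c_t < 20 | c_t > 100))
      warning("c_t outside the fitted range [20, 100]; extrapolating")
    polyval(object[[tolower(quantity)]], c_t)
  }
}

#' @export
print.size_perf_model <- function(x, ...) {
  cat("Size-dependent SSP performance model\n")
  cat(sprintf("  TC(n_t) = %.4e * n_t + %.4f  [s]\n",
              x$tc_slope, x$tc_intercept))
  cat(sprintf(
    "  Q3(n_t) = %.4f / (1 + exp((%.4f - log2 n_t)/%.4f))^%.4f + %.4f\n",
    x$q3[["amplitude"]], x$q3[["midpoint"]], x$q3[["scale"]],
    x$q3[["asymmetry"]], x$q3[["baseline"]]))
  cat(sprintf(
    "  Q8(n_t) = %.4f / (1 + exp((%.4f - log2 n_t)/%.4f)) + %.4f\n",
    x$q8[["amplitude"]], x$q8[["midpoint"]], x$q8[["scale"]],
    x$q8[["baseline"]]))
  cat("  note:", x$hardware_note, "\n")
  invisible(x)
}

#' @export
print.homology_perf_model <- function(x, ...) {
  cat("Homology-dependent SSP performance model\n")
  cat("  TC(n_t): quadratic coefficients",
      paste(signif(x$tc, 5), collapse = ", "), "\n")
  cat("  Q3(c_t): cubic coefficients",
      paste(signif(x$q3, 5), collapse = ", "), "\n")
  cat("  Q8(c_t): cubic coefficients",
      paste(signif(x$q8, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Fit size-dependent performance curves to measured points
#'
#' Refits the curve forms of [size_perf_model()] to user-measured
#' `(n_t, y)` points: ordinary least squares for the linear time cost,
#' and bounded Levenberg-Marquardt nonlinear least squares
#' (`minpack.lm::nlsLM`, convergence tolerance 1e-10) for the logistic
#' accuracy curves over `log2(n_t)`. Starting values are derived from the
#' data: baseline = min(y), amplitude = max(y) - min(y), midpoint =
#' `log2(n_t)` at the half rise, scale = 2, asymmetry = 1; amplitude,
#' scale and asymmetry are bounded below by small positive constants, so
#' the fit is deterministic given the points.
#'
#' @param n_t dataset sizes (>= 1) of the measured points.
#' @param y measured values (seconds for `"TC"`, fractions for accuracy).
#' @param quantity `"TC"` (linear, >= 2 points), `"Q3"` (5-parameter
#'   generalized logistic, >= 6 points) or `"Q8"` (4-parameter logistic,
#'   >= 5 points).
#' @return An object of class `ssp_perf_fit` with elements
#'   `coefficients`, `residuals`, `rss`, `quantity`, `fitted`; supports
#'   `coef()`, `print()` and `predict(fit, n_t = ...)`.
#' @export
fit_size_model <- function(n_t, y, quantity = c("TC", "Q3", "Q8")) {
  quantity <- match.arg(quantity)
  if (length(n_t) != length(y)) stop("length mismatch")
  if (any(n_t < 1)) stop("'n_t' must be >= 1")
  if (quantity == "TC") {
    if (length(y) < 2) stop("need >= 2 points for the linear fit")
    fm <- stats::lm(y ~ n_t)
    coefs <- c(tc_slope = unname(stats::coef(fm)[2]),
               tc_intercept = unname(stats::coef(fm)[1]))
    fitted <- unname(stats::fitted(fm))
  } else {
    npar <- if (quantity == "Q3") 5L else 4L
    if (length(y) < npar)
      stop("need at least ", npar, " points for the ", quantity, " fit")
    x <- log2(n_t)
    start <- list(amplitude = max(y) - min(y),
                  midpoint = x[which.min(abs(y - (min(y) + max(y)) / 2))],
                  scale = 2, baseline = min(y))
    lower <- c(amplitude = 1e-6, midpoint = min(x) - 10, scale = 1e-3,
               baseline = -1)
    upper <- c(amplitude = 1, midpoint = max(x) + 10, scale = 50,
               baseline = 1)
    if (quantity == "Q3") {
      form <- y ~ amplitude /
        (1 + exp((midpoint - x) / scale))^asymmetry + baseline
      start$asymmetry <- 1
      lower <- c(lower, asymmetry = 1e-3)
      upper <- c(upper, asymmetry = 20)
    } else {
      form <- y ~ amplitude / (1 + exp((midpoint - x) / scale)) + baseline
    }
    fm <- minpack.lm::nlsLM(
      form, data = data.frame(x = x, y = y), start = start,
      lower = lower[names(start)], upper = upper[names(start)],
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 500))
    coefs <- stats::coef(fm)
    fitted <- unname(stats::fitted(fm))
  }
  new_perf_fit(coefs, y, fitted, quantity, model_kind = "size")
}

#' Fit homology-dependent performance curves to measured points
#'
#' Ordinary polynomial least squares in the forms of
#' [homology_perf_model()]: quadratic in `n_t` for `"TC"` (>= 3 points
#' at distinct sizes), cubic in `c_t` for `"Q3"`/`"Q8"` (>= 4 points at
#' distinct cutoffs). Coefficients are returned highest degree first.
#'
#' @param x dataset sizes (`"TC"`) or identity cutoffs in percent.
#' @param y measured values.
#' @param quantity `"TC"`, `"Q3"` or `"Q8"`.
#' @return An `ssp_perf_fit` object, as in [fit_size_model()].
#' @export
fit_homology_model <- function(x, y, quantity = c("TC", "Q3", "Q8")) {
  quantity <- match.arg(quantity)
  if (length(x) != length(y)) stop("length mismatch")
  degree <- if (quantity == "TC") 2L else 3L
  if (length(unique(x)) <= degree)
    stop("need > ", degree, " distinct x values for a degree-", degree,
         " polynomial")
  fm <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  coefs <- rev(unname(stats::coef(fm)))   # highest degree first
  names(coefs) <- paste0("c", seq(degree, 0))
  new_perf_fit(coefs, y, unname(stats::fitted(fm)), quantity,
               model_kind = "homology")
}

new_perf_fit <- function(coefs, y, fitted, quantity, model_kind) {
  res <- y - fitted
  structure(list(coefficients = coefs, residuals = res,
                 rss = sum(res^2), fitted = fitted,
                 quantity = quantity, model_kind = model_kind),
            class = "ssp_perf_fit")
}

#' @export
coef.ssp_perf_fit <- function(object, ...) object$coefficients

#' @export
residuals.ssp_perf_fit <- function(object, ...) object$residuals

#' @export
print.ssp_perf_fit <- function(x, ...) {
  cat(sprintf("%s-model fit of %s (%d points, RSS %.4g)\n",
              x$model_kind, x$quantity, length(x$residuals), x$rss))
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' @describeIn fit_size_model Evaluate a fitted curve at new inputs
#'   (`n_t` for size-model fits and homology `"TC"`, `c_t` for homology
#'   accuracy fits).
#' @param object an `ssp_perf_fit`.
#' @param n_t,c_t evaluation points.
#' @param ... unused.
#' @export
predict.ssp_perf_fit <- function(object, n_t = NULL, c_t = NULL, ...) {
  cf <- object$coefficients
  if (object$model_kind == "homology") {
    x <- if (object$quantity == "TC") n_t else c_t
    if (is.null(x)) stop("evaluation points required")
    return(polyval(cf, x))
  }
  if (is.null(n_t)) stop("'n_t' required")
  if (object$quantity == "TC")
    cf[["tc_slope"]] * n_t + cf[["tc_intercept"]]
  else
    gen_logistic(cf, log2(n_t))
}
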