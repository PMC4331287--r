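#' @title Log-log allometric models
#' @description Power-law relationships y = 10^a * x^b are fitted as
#'   straight lines on log10-log10 axes by ordinary least squares, the
#'   conventional choice when the goal is prediction of y at a given x
#'   (rather than estimating a structural scaling exponent, where reduced
#'   major axis is sometimes preferred). All internal arithmetic is in
#'   log base 10, matching the standard presentation of allometric
#'   equations; natural logs are never exposed.
#' @name loglog_model
#' @keywords internal
NULL

check_pairs <- function(pairs, min_n = 3L) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs)
  if (!is.data.frame(pairs) || !all(c("x", "y") %in% names(pairs))) {
    abort_validation("pairs must be a data frame with columns x and y")
  }
  if (nrow(pairs) < min_n) {
    abort_validation("need at least ", min_n, " pairs, got ", nrow(pairs))
  }
  v <- c(pairs$x, pairs$y)
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort_validation("all pair values must be strictly positive and finite")
  }
  pairs
}

new_loglog_model <- function(a, b, n = NA_integer_, r = NA_real_,
                             residual_sd = NA_real_, mean_log_x = NA_real_,
                             ss_log_x = NA_real_, residuals = NULL,
                             x_role = NA_character_, y_role = NA_character_,
                             a_ci = c(NA_real_, NA_real_),
                             b_ci = c(NA_real_, NA_real_),
                             a_se = NA_real_, b_se = NA_real_,
                             boot = NULL, provenance = "fitted") {
  structure(list(
    a = a, b = b, n = n, r = r,
    residual_sd = residual_sd, mean_log_x = mean_log_x, ss_log_x = ss_log_x,
    residuals = residuals, x_role = x_role, y_role = y_role,
    a_ci = a_ci, b_ci = b_ci, a_se = a_se, b_se = b_se,
    boot = boot, provenance = provenance
  ), class = "loglog_model")
}

#' Fit a log10-log10 allometric regression
#'
#' Ordinary least squares on log10-transformed (x, y) pairs. Log
#' transformation homogenises the variances of size measurements and makes
#' the power law y = 10^a * x^b linear. The returned model carries the
#' fit diagnostics needed for analytic prediction intervals; bootstrap
#' coefficient intervals are unset until [bootstrap_fit()] is run.
#'
#' @param pairs data frame with positive columns `x` and `y`
#'   (see [paired_view()]).
#' @param x_role,y_role optional measurement role labels recorded on the
#'   model.
#' @return A `loglog_model` with intercept `a`, slope `b`, sample size `n`,
#'   Pearson correlation `r` of the log10 pairs, residual standard deviation
#'   (n - 2 denominator), predictor log-mean and centred sum of squares, and
#'   the log10 residuals.
#' @export
#' @examples
#' fit_loglog(data.frame(x = c(1, 10, 100), y = c(10^0.5, 10^2.5, 10^4.5)))
fit_loglog <- function(pairs, x_role = NA_character_, y_role = NA_character_) {
  pairs <- check_pairs(pairs)
  lx <- log10(pairs$x)
  ly <- log10(pairs$y)
  n <- length(lx)
  if (stats::var(lx) < .Machine$double.eps) {
    abort_validation("constant predictor: zero spread in log10(x)")
  }
  fit <- stats::lm(ly ~ lx)
  coefs <- stats::coef(fit)
  res <- stats::residuals(fit)
  new_loglog_model(
    a = unname(coefs[1L]), b = unname(coefs[2L]), n = n,
    r = if (stats::var(ly) < .Machine$double.eps) NA_real_ else stats::cor(lx, ly),
    residual_sd = sqrt(sum(res^2) / (n - 2)),
    mean_log_x = mean(lx),
    ss_log_x = sum((lx - mean(lx))^2),
    residuals = unname(res),
    x_role = x_role, y_role = y_role
  )
}

#' Pearson correlation of log10-transformed pairs
#'
#' The product-moment correlation between log10(x) and log10(y); squared it
#' equals the coefficient of determination of the log-log OLS fit.
#'
#' @inheritParams fit_loglog
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(pairs) {
  pairs <- check_pairs(pairs)
  lx <- log10(pairs$x)
  ly <- log10(pairs$y)
  if (stats::var(lx) < .Machine$double.eps ||
      stats::var(ly) < .Machine$double.eps) {
    abort_validation("constant variate: correlation undefined")
  }
  stats::cor(lx, ly)
}

#' Build a model from published coefficients
#'
#' Wraps externally published intercept/slope values (with optional
#' bootstrap confidence intervals and standard errors quoted alongside them)
#' as a `loglog_model`. Such a model predicts points but carries no fit
#' diagnostics, so it cannot produce analytic prediction intervals — that
#' limitation is signalled explicitly by [prediction_interval()].
#'
#' @param a,b intercept and slope on the log10 scale.
#' @param a_ci,b_ci optional published 95% confidence intervals.
#' @param a_se,b_se optional published standard errors.
#' @param r optional published Pearson correlation.
#' @param x_role,y_role measurement roles.
#' @return A `loglog_model` with `provenance = "published"`.
#' @export
published_model <- function(a, b, a_ci = c(NA_real_, NA_real_),
                            b_ci = c(NA_real_, NA_real_),
                            a_se = NA_real_, b_se = NA_real_, r = NA_real_,
                            x_role = NA_character_, y_role = NA_character_) {
  stopifnot(is_scalar_number(a), is_scalar_number(b))
  new_loglog_model(a = a, b = b, r = r, a_ci = a_ci, b_ci = b_ci,
                   a_se = a_se, b_se = b_se,
                   x_role = x_role, y_role = y_role, provenance = "published")
}

has_diagnostics <- function(model) {
  is_scalar_number(model$residual_sd) && is_scalar_number(model$ss_log_x) &&
    !is.na(model$n)
}

#' Predict on the natural scale
#'
#' Evaluates the fitted power law at `x0`: 10^(a + b * log10(x0)).
#'
#' @param model a `loglog_model`.
#' @param x0 positive predictor value in the model's x units.
#' @return Predicted value in the model's y units.
#' @export
#' @examples
#' m <- published_model(a = -0.56913, b = 1.10776, x_role = "dcl", y_role = "svl")
#' predict_point(m, 1400)  # snout-vent length (cm) for a 1400 mm skull
predict_point <- function(model, x0) {
  stopifnot(inherits(model, "loglog_model"))
  check_positive_scalar(x0, "x0")
  10^(model$a + model$b * log10(x0))
}

#' Prediction interval for a new observation
#'
#' Natural-scale prediction limits for a single new individual at `x0`.
#' The default analytic interval is the classical OLS prediction interval
#' on the log10 scale,
#' point +/- t(level, n-2) * s * sqrt(1 + 1/n + (log10 x0 - mean)^2 / SS),
#' back-transformed by 10^. The back-transformed interval is multiplicative:
#' upper/point equals point/lower (log-symmetry). The `"bootstrap"` method
#' instead resamples the fitted coefficients (one bootstrap replicate per
#' draw) and adds a resampled log residual, then takes the level-quantile of
#' the absolute log10 deviations as a symmetric half-width — the same
#' multiplicative contract, without the t/normality assumption.
#'
#' @param model a fitted `loglog_model` (published-coefficient models lack
#'   the required diagnostics and raise an error).
#' @param x0 positive predictor value.
#' @param level coverage, default 0.95.
#' @param method `"analytic"` (default) or `"bootstrap"` (requires
#'   [bootstrap_fit()] to have been run with `keep_replicates = TRUE`).
#' @return A `prediction_result`: list with `x0`, `point`, `lower`, `upper`,
#'   `log10_halfwidth` and `level`.
#' @export
prediction_interval <- function(model, x0, level = 0.95,
                                method = c("analytic", "bootstrap")) {
  stopifnot(inherits(model, "loglog_model"))
  method <- match.arg(method)
  check_positive_scalar(x0, "x0")
  if (!is_scalar_number(level) || level <= 0 || level >= 1) {
    abort_validation("level must be in (0, 1)")
  }
  if (!has_diagnostics(model)) {
    abort_validation("model lacks fit diagnostics (built from published ",
                     "coefficients alone); analytic prediction limits require ",
                     "a model fitted to calibration data")
  }
  log_point <- model$a + model$b * log10(x0)
  if (method == "analytic") {
    tq <- stats::qt(1 - (1 - level) / 2, df = model$n - 2)
    half <- tq * model$residual_sd *
      sqrt(1 + 1 / model$n + (log10(x0) - model$mean_log_x)^2 / model$ss_log_x)
  } else {
    if (is.null(model$boot) || is.null(model$boot$coef)) {
      abort_validation("bootstrap prediction interval requires bootstrap ",
                       "replicates: run bootstrap_fit(..., keep_replicates = TRUE)")
    }
    coefs <- model$boot$coef
    # one residual draw per coefficient replicate, seeded off the stored
    # bootstrap seed so the interval is deterministic
    set.seed((model$boot$seed + 1L) %% .Machine$integer.max)
    res <- sample(model$residuals, nrow(coefs), replace = TRUE)
    sim <- coefs[, 1L] + coefs[, 2L] * log10(x0) + res
    half <- unname(stats::quantile(abs(sim - log_point), level))
  }
  structure(list(
    x0 = x0,
    point = 10^log_point,
    lower = 10^(log_point - half),
    upper = 10^(log_point + half),
    log10_halfwidth = half,
    level = level,
    method = method
  ), class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%.4g  [%s%% PI: %.4g - %.4g]  (%s, log10 halfwidth %.4g)\n",
              x$point, format(100 * x$level), x$lower, x$upper,
              x$method, x$log10_halfwidth))
  invisible(x)
}

#' @export
print.loglog_model <- function(x, ...) {
  rel <- if (!is.na(x$x_role) && !is.na(x$y_role)) {
    sprintf(" [%s (%s) -> %s (%s)]", x$x_role, role_unit(x$x_role),
            x$y_role, role_unit(x$y_role))
  } else ""
  cat(sprintf("Log10-log10 allometric model%s, %s coefficients\n",
              rel, x$provenance))
  cat(sprintf("  log10(y) = %.5f + %.5f * log10(x)\n", x$a, x$b))
  if (!is.na(x$r)) cat(sprintf("  Pearson r (log scale): %.4f\n", x$r))
  if (!is.na(x$n)) {
    cat(sprintf("  n = %d, residual sd (log10) = %.4f\n", x$n, x$residual_sd))
  }
  if (!any(is.na(x$a_ci))) {
    cat(sprintf("  a: 95%% CI (%.5f, %.5f)  SE %.4f\n",
                x$a_ci[1L], x$a_ci[2L], x$a_se))
    cat(sprintf("  b: 95%% CI (%.5f, %.5f)  SE %.4f\n",
                x$b_ci[1L], x$b_ci[2L], x$b_se))
  }
  invisible(x)
}
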