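#' Bootstrap configuration
#'
#' Settings for nonparametric case-resampling of (x, y) pairs. The default
#' of 1000 replications is the customary choice for percentile intervals on
#' small morphometric panels; the bootstrap makes no distributional
#' assumption, which suits the small samples typical of comparative and
#' paleontological datasets.
#'
#' @param n_reps number of bootstrap replications (>= 1), default 1000.
#' @param seed integer random seed; fixed default so every run is
#'   reproducible unless the caller chooses otherwise.
#' @param ci_level confidence-interval coverage in (0, 1), default 0.95.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(n_reps = 1000L, seed = 20150217L, ci_level = 0.95) {
  if (!is_scalar_number(n_reps) || n_reps < 1) {
    abort_validation("n_reps must be >= 1")
  }
  if (!is_scalar_number(seed)) abort_validation("seed must be a finite number")
  if (!is_scalar_number(ci_level) || ci_level <= 0 || ci_level >= 1) {
    abort_validation("ci_level must be in (0, 1)")
  }
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 ci_level = ci_level), class = "bootstrap_config")
}

# Vectorised OLS over an index matrix of resamples: one row per replicate.
# Returns cbind(a, b); rows whose resampled predictor is (numerically)
# constant come back NA and are redrawn by the caller.
resample_coefs <- function(lx, ly, idx) {
  n <- length(lx)
  bx <- matrix(lx[idx], nrow = nrow(idx))
  by <- matrix(ly[idx], nrow = nrow(idx))
  mx <- rowMeans(bx)
  my <- rowMeans(by)
  cx <- bx - mx
  sxx <- rowSums(cx^2)
  sxy <- rowSums(cx * (by - my))
  b <- ifelse(sxx > n * .Machine$double.eps * max(abs(lx))^2 + 1e-300,
              sxy / sxx, NA_real_)
  cbind(a = my - b * mx, b = b)
}

#' Fit with bootstrap coefficient intervals
#'
#' Fits the log10-log10 OLS model and attaches bootstrap uncertainty for the
#' coefficients: pairs are resampled with replacement (case resampling) and
#' the model refitted per replicate; the standard error is the standard
#' deviation of the replicate coefficients and the confidence interval is
#' the percentile interval at `ci_level`. A resample whose predictor values
#' are all identical cannot be fitted and is redrawn (bounded retries).
#' Output is deterministic for a fixed seed.
#'
#' @inheritParams fit_loglog
#' @param config a [bootstrap_config()].
#' @param keep_replicates keep the replicate coefficient matrix on the model
#'   (needed for the bootstrap prediction-interval method and for replicate
#'   export); default `TRUE`.
#' @return A `loglog_model` with `a_ci`, `b_ci`, `a_se`, `b_se` and a `boot`
#'   record (config, seed and optionally the replicate matrix) populated.
#' @export
#' @examples
#' set.seed(1)
#' x <- 10^runif(20, 1, 3)
#' y <- 10^(0.2 + 0.8 * log10(x) + rnorm(20, 0, 0.05))
#' bootstrap_fit(data.frame(x = x, y = y), bootstrap_config(n_reps = 200))
bootstrap_fit <- function(pairs, config = bootstrap_config(),
                          x_role = NA_character_, y_role = NA_character_,
                          keep_replicates = TRUE) {
  stopifnot(inherits(config, "bootstrap_config"))
  model <- fit_loglog(pairs, x_role = x_role, y_role = y_role)
  pairs <- check_pairs(pairs)
  lx <- log10(pairs$x)
  ly <- log10(pairs$y)
  n <- length(lx)
  R <- config$n_reps

  set.seed(config$seed)
  idx <- matrix(sample.int(n, n * R, replace = TRUE), nrow = R)
  coefs <- resample_coefs(lx, ly, idx)
  retries <- 0L
  while (anyNA(coefs[, "b"]) && retries < 100L) {
    bad <- which(is.na(coefs[, "b"]))
    idx_bad <- matrix(sample.int(n, n * length(bad), replace = TRUE),
                      nrow = length(bad))
    coefs[bad, ] <- resample_coefs(lx, ly, idx_bad)
    retries <- retries + 1L
  }
  if (anyNA(coefs[, "b"])) {
    abort_validation("bootstrap failed: constant-predictor resamples persisted ",
                     "after 100 redraw rounds")
  }

  alpha <- (1 - config$ci_level) / 2
  model$a_ci <- unname(stats::quantile(coefs[, "a"], c(alpha, 1 - alpha)))
  model$b_ci <- unname(stats::quantile(coefs[, "b"], c(alpha, 1 - alpha)))
  model$a_se <- stats::sd(coefs[, "a"])
  model$b_se <- stats::sd(coefs[, "b"])
  model$boot <- list(
    n_reps = R, seed = config$seed, ci_level = config$ci_level,
    coef = if (keep_replicates) coefs else NULL
  )
  model
}

#' Export bootstrap replicate coefficients
#'
#' Writes the replicate (a, b) matrix of a bootstrapped model to CSV for
#' audit, one row per replication.
#'
#' @param model a `loglog_model` from [bootstrap_fit()] with
#'   `keep_replicates = TRUE`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_replicates <- function(model, path) {
  stopifnot(inherits(model, "loglog_model"))
  if (is.null(model$boot) || is.null(model$boot$coef)) {
    abort_validation("model carries no bootstrap replicates")
  }
  df <- data.frame(replicate = seq_len(nrow(model$boot$coef)),
                   a = model$boot$coef[, "a"], b = model$boot$coef[, "b"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a model to a flat record
#'
#' Flattens every model field (coefficients, diagnostics, bootstrap CIs/SEs,
#' roles, provenance, bootstrap config and seed) into a named list suitable
#' for JSON export; the replicate matrix itself is not included.
#'
#' @param model a `loglog_model`.
#' @return Named list of scalars and length-2 vectors.
#' @export
model_record <- function(model) {
  stopifnot(inherits(model, "loglog_model"))
  list(
    a = model$a, b = model$b, n = model$n, r = model$r,
    residual_sd = model$residual_sd, mean_log_x = model$mean_log_x,
    ss_log_x = model$ss_log_x,
    a_ci = model$a_ci, b_ci = model$b_ci,
    a_se = model$a_se, b_se = model$b_se,
    x_role = model$x_role, y_role = model$y_role,
    x_unit = if (is.na(model$x_role)) NA_character_ else role_unit(model$x_role),
    y_unit = if (is.na(model$y_role)) NA_character_ else role_unit(model$y_role),
    provenance = model$provenance,
    boot_n_reps = if (is.null(model$boot)) NA_integer_ else model$boot$n_reps,
    boot_seed = if (is.null(model$boot)) NA_integer_ else model$boot$seed,
    boot_ci_level = if (is.null(model$boot)) NA_real_ else model$boot$ci_level
  )
}
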