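# Published coefficient set for the four-stage crocodilian allometry chain:
# log10-log10 OLS fits on extant-crocodilian calibration data (DCL->SVL and
# SVL->TTL from Caiman latirostris ontogenetic series; TTL->BM and BM->BF
# across living crocodilian species), with bootstrap 95% CIs and SEs from
# 1000 case-resampling replications, and Pearson r of the log pairs.
.published_coefs <- data.frame(
  stage  = c("svl", "ttl", "bm", "bf"),
  x_role = c("dcl", "svl", "ttl", "bm"),
  y_role = c("svl", "ttl", "bm", "bf"),
  a      = c(-0.56913, 0.41689, -5.1240, 2.21779),
  a_lo   = c(-0.71309, 0.31918, -5.76438, 2.01402),
  a_hi   = c(-0.42518, 0.51459, -4.48354, 2.42156),
  a_se   = c(0.0588, 0.0425, 0.3488, 0.0942),
  b      = c(1.10776, 0.91905, 2.9221, 0.66776),
  b_lo   = c(1.02959, 0.85267, 2.6513, 0.55584),
  b_hi   = c(1.18592, 0.98543, 3.19297, 0.77968),
  b_se   = c(0.0322, 0.0296, 0.1496, 0.0539),
  r      = c(0.9844, 0.9836, 0.9797, 0.9380),
  stringsAsFactors = FALSE
)

#' Published regression coefficients for the estimation chain
#'
#' The published log10-scale intercepts and slopes (with bootstrap 95%
#' confidence intervals, standard errors and Pearson correlations) for the
#' four allometric relationships DCL to SVL, SVL to TTL, TTL to BM and BM
#' to BF in extant crocodilians.
#'
#' @return Data frame with one row per chain stage.
#' @export
published_coefficients <- function() .published_coefs

new_model_chain <- function(svl_model, ttl_model, bm_model, bf_model,
                            provenance) {
  chain <- structure(list(svl_model = svl_model, ttl_model = ttl_model,
                          bm_model = bm_model, bf_model = bf_model,
                          provenance = provenance), class = "model_chain")
  validate_model_chain(chain)
}

chain_stage_models <- function(chain) {
  list(chain$svl_model, chain$ttl_model, chain$bm_model, chain$bf_model)
}

validate_model_chain <- function(chain) {
  models <- chain_stage_models(chain)
  expected <- list(c("dcl", "svl"), c("svl", "ttl"), c("ttl", "bm"), c("bm", "bf"))
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (!inherits(m, "loglog_model")) {
      abort_validation("chain stage ", i, " is not a loglog_model")
    }
    if (!identical(c(m$x_role, m$y_role), expected[[i]])) {
      abort_validation("broken chain linkage at stage ", i, ": roles (",
                       m$x_role, " -> ", m$y_role, "), expected (",
                       expected[[i]][1L], " -> ", expected[[i]][2L], ")")
    }
  }
  # head-to-tail: each stage's response feeds the next stage's predictor
  for (i in 1:3) {
    if (!identical(models[[i]]$y_role, models[[i + 1L]]$x_role)) {
      abort_validation("chain stages ", i, " and ", i + 1L, " are not linked")
    }
  }
  chain
}

#' Chain of published-coefficient models
#'
#' Builds the four-stage model chain from the embedded published
#' coefficients. The published CIs and SEs are attached as metadata; fit
#' diagnostics are absent, so the chain yields point estimates only (no
#' prediction limits — use [fit_chain()] on calibration data for those).
#'
#' @return A `model_chain` with `provenance = "published"`.
#' @seealso [estimate_from_dcl()], [fit_chain()]
#' @export
#' @examples
#' published_chain()$bm_model
published_chain <- function() {
  tab <- .published_coefs
  models <- lapply(seq_len(nrow(tab)), function(i) {
    published_model(
      a = tab$a[i], b = tab$b[i],
      a_ci = c(tab$a_lo[i], tab$a_hi[i]), b_ci = c(tab$b_lo[i], tab$b_hi[i]),
      a_se = tab$a_se[i], b_se = tab$b_se[i], r = tab$r[i],
      x_role = tab$x_role[i], y_role = tab$y_role[i]
    )
  })
  new_model_chain(models[[1L]], models[[2L]], models[[3L]], models[[4L]],
                  provenance = "published")
}

#' Fit the estimation chain to calibration data
#'
#' Fits and bootstraps all four stages: (dcl, svl) and (svl, ttl) pairs are
#' taken from `svl_table` (a Caiman-latirostris-style ontogenetic panel) and
#' (ttl, bm) and (bm, bf) pairs from `body_table` (a cross-species panel of
#' living crocodilians). Missing values are handled pairwise: a record is
#' dropped only from the regressions it cannot serve. Stage seeds are
#' derived deterministically from `config$seed`.
#'
#' @param svl_table [calibration_table()] supplying dcl, svl, ttl.
#' @param body_table [calibration_table()] supplying ttl, bm, bf.
#' @param config a [bootstrap_config()].
#' @return A fully fitted, bootstrapped `model_chain` able to produce
#'   per-stage prediction limits.
#' @export
fit_chain <- function(svl_table, body_table, config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  spec <- list(
    list(table = svl_table,  x = "dcl", y = "svl"),
    list(table = svl_table,  x = "svl", y = "ttl"),
    list(table = body_table, x = "ttl", y = "bm"),
    list(table = body_table, x = "bm",  y = "bf")
  )
  models <- vector("list", 4L)
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    stage_cfg <- bootstrap_config(
      n_reps = config$n_reps,
      seed = (config$seed + i * 1000003L) %% .Machine$integer.max,
      ci_level = config$ci_level
    )
    models[[i]] <- tryCatch(
      bootstrap_fit(paired_view(s$table, s$x, s$y), stage_cfg,
                    x_role = s$x, y_role = s$y),
      error = function(e) {
        abort_validation("chain stage ", i, " (", s$x, " -> ", s$y,
                         ") failed: ", conditionMessage(e))
      }
    )
  }
  new_model_chain(models[[1L]], models[[2L]], models[[3L]], models[[4L]],
                  provenance = "fitted")
}

point_only_result <- function(x0, point) {
  structure(list(x0 = x0, point = point, lower = NA_real_, upper = NA_real_,
                 log10_halfwidth = NA_real_, level = NA_real_,
                 method = "none"), class = "prediction_result")
}

#' Run the four-stage estimation chain for one skull measurement
#'
#' Chains the point predictions DCL -> SVL -> TTL -> BM -> BF, each stage
#' feeding its point estimate (never its limits) into the next, with no
#' intermediate rounding. With a fitted chain, each stage additionally gets
#' 95% prediction limits evaluated at its incoming point estimate; these are
#' per-regression limits, so the total uncertainty accumulated along the
#' chain is deliberately understated (see the package vignette) — an
#' explicit Monte-Carlo full-chain propagation is available via
#' [chain_mc_intervals()] for comparison. With a published-coefficient
#' chain, limits are absent and flagged.
#'
#' @param dcl dorsal cranial length of the specimen, millimetres.
#' @param chain a `model_chain` from [published_chain()] or [fit_chain()].
#' @param level prediction-limit coverage for fitted chains, default 0.95.
#' @return A `chain_result`: the input `dcl`, one `prediction_result` per
#'   stage (`svl`, `ttl` in cm, `bm` in kg, `bf` in N), whether limits are
#'   available, and the chain provenance.
#' @export
#' @examples
#' res <- estimate_from_dcl(1400, published_chain())
#' res$bm$point  # body mass, kg
estimate_from_dcl <- function(dcl, chain, level = 0.95) {
  stopifnot(inherits(chain, "model_chain"))
  check_positive_scalar(dcl, "dcl")
  validate_model_chain(chain)
  models <- chain_stage_models(chain)
  with_limits <- all(vapply(models, has_diagnostics, logical(1L)))

  x <- dcl
  stages <- vector("list", 4L)
  for (i in seq_along(models)) {
    if (with_limits) {
      stages[[i]] <- prediction_interval(models[[i]], x, level = level)
    } else {
      stages[[i]] <- point_only_result(x, predict_point(models[[i]], x))
    }
    x <- stages[[i]]$point
  }
  structure(list(
    dcl = dcl,
    svl = stages[[1L]], ttl = stages[[2L]], bm = stages[[3L]], bf = stages[[4L]],
    limits_available = with_limits,
    level = if (with_limits) level else NA_real_,
    provenance = chain$provenance
  ), class = "chain_result")
}

#' Monte-Carlo propagation of full-chain uncertainty
#'
#' Per-stage prediction limits (the default output of [estimate_from_dcl()])
#' quantify each regression's own uncertainty at its incoming point
#' estimate; they do not accumulate uncertainty across stages. This
#' function propagates instead: each draw samples one bootstrap coefficient
#' replicate plus one resampled log residual per stage and pushes the value
#' through the whole chain, giving percentile intervals for every stage that
#' reflect all upstream uncertainty.
#'
#' @param chain a fitted, bootstrapped `model_chain` (replicates kept).
#' @param dcl skull length, mm.
#' @param n_draws number of Monte-Carlo draws, default 2000.
#' @param level interval coverage, default 0.95.
#' @param seed integer seed.
#' @return A `chain_mc` object: per-stage point estimates with Monte-Carlo
#'   `lower`/`upper` percentile limits.
#' @export
chain_mc_intervals <- function(chain, dcl, n_draws = 2000L, level = 0.95,
                               seed = 20150217L) {
  stopifnot(inherits(chain, "model_chain"))
  check_positive_scalar(dcl, "dcl")
  models <- chain_stage_models(chain)
  ok <- vapply(models, function(m) {
    has_diagnostics(m) && !is.null(m$boot) && !is.null(m$boot$coef)
  }, logical(1L))
  if (!all(ok)) {
    abort_validation("Monte-Carlo propagation requires a fitted chain with ",
                     "bootstrap replicates at every stage")
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  lx <- rep(log10(dcl), n_draws)
  out <- vector("list", 4L)
  names(out) <- c("svl", "ttl", "bm", "bf")
  point <- dcl
  for (i in seq_along(models)) {
    m <- models[[i]]
    pick <- sample.int(nrow(m$boot$coef), n_draws, replace = TRUE)
    res <- sample(m$residuals, n_draws, replace = TRUE)
    lx <- m$boot$coef[pick, 1L] + m$boot$coef[pick, 2L] * lx + res
    point <- predict_point(m, point)
    alpha <- (1 - level) / 2
    qs <- stats::quantile(10^lx, c(alpha, 1 - alpha), names = FALSE)
    out[[i]] <- list(point = point, lower = qs[1L], upper = qs[2L])
  }
  structure(list(dcl = dcl, stages = out, n_draws = n_draws, level = level,
                 seed = seed), class = "chain_mc")
}

#' @export
print.model_chain <- function(x, ...) {
  cat("Four-stage allometric estimation chain (", x$provenance,
      " coefficients)\n", sep = "")
  for (m in chain_stage_models(x)) {
    cat(sprintf("  %s -> %s: log10(y) = %.5f + %.5f * log10(x)\n",
                m$x_role, m$y_role, m$a, m$b))
  }
  invisible(x)
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("Chain estimates for DCL = %g mm (%s coefficients)\n",
              x$dcl, x$provenance))
  labels <- c(svl = "Snout-vent length (cm)", ttl = "Total length (cm)",
              bm = "Body mass (kg)", bf = "Bite force (N)")
  for (stage in names(labels)) {
    s <- x[[stage]]
    if (x$limits_available) {
      cat(sprintf("  %-24s %10.1f  (%.1f - %.1f)\n", labels[[stage]],
                  s$point, s$lower, s$upper))
    } else {
      cat(sprintf("  %-24s %10.1f  (limits unavailable: published coefficients)\n",
                  labels[[stage]], s$point))
    }
  }
  invisible(x)
}

#' @export
print.chain_mc <- function(x, ...) {
  cat(sprintf("Monte-Carlo full-chain propagation, DCL = %g mm (%d draws)\n",
              x$dcl, x$n_draws))
  for (stage in names(x$stages)) {
    s <- x$stages[[stage]]
    cat(sprintf("  %-4s %12.1f  (%.1f - %.1f)\n", stage, s$point,
                s$lower, s$upper))
  }
  invisible(x)
}
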