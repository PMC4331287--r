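#' Specification for one synthetic allometric relationship
#'
#' Describes a simulated calibration panel: `n` specimens with predictor `x`
#' drawn log-uniformly over `x_range` (so leverage is spread evenly across
#' the size range on the log scale, where the model is linear) and response
#' generated from the power law log10(y) = true_a + true_b * log10(x) plus
#' Gaussian log10 noise of standard deviation `noise_sd` (i.e. lognormal
#' multiplicative scatter, the error structure allometric data typically
#' show).
#'
#' @param n number of rows, >= 3.
#' @param true_a,true_b generating log10 intercept and slope.
#' @param noise_sd log10 residual standard deviation, >= 0.
#' @param x_range length-2 positive vector, min < max, natural scale.
#' @param seed integer seed.
#' @param missing_rate fraction of measurement cells blanked at random when
#'   the relationship is assembled into a table, in \[0, 1).
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n, true_a, true_b, noise_sd, x_range,
                       seed = 20150217L, missing_rate = 0) {
  if (!is_scalar_number(n) || n < 3) abort_validation("n must be >= 3")
  stopifnot(is_scalar_number(true_a), is_scalar_number(true_b))
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    abort_validation("noise_sd must be >= 0")
  }
  if (length(x_range) != 2L || any(!is.finite(x_range)) ||
      x_range[1L] <= 0 || x_range[1L] >= x_range[2L]) {
    abort_validation("x_range must satisfy 0 < min < max")
  }
  if (!is_scalar_number(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    abort_validation("missing_rate must be in [0, 1)")
  }
  structure(list(n = as.integer(n), true_a = true_a, true_b = true_b,
                 noise_sd = noise_sd, x_range = as.numeric(x_range),
                 seed = as.integer(seed), missing_rate = missing_rate),
            class = "panel_spec")
}

#' Simulate (x, y) pairs from a power law with lognormal scatter
#'
#' @param spec a [panel_spec()].
#' @return Data frame with positive columns `x` and `y`; deterministic for
#'   a fixed seed.
#' @export
#' @examples
#' simulate_relationship(panel_spec(5, true_a = 0.4, true_b = 0.9,
#'                                  noise_sd = 0.05, x_range = c(10, 500)))
simulate_relationship <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  lx <- stats::runif(spec$n, log10(spec$x_range[1L]), log10(spec$x_range[2L]))
  ly <- spec$true_a + spec$true_b * lx +
    stats::rnorm(spec$n, 0, spec$noise_sd)
  data.frame(x = 10^lx, y = 10^ly)
}

# Default generating parameters: the published coefficient set, with log10
# noise levels in the 0.03-0.06 band so simulated panels show correlations
# comparable to real extant-crocodilian calibration data. Predictor ranges
# cover extant animals only (skull 20-700 mm), so a 1400 mm fossil skull is
# an extrapolation, as it is for the real calibration.
.panel_defaults <- list(
  dcl_range = c(20, 700),     # mm, extant skull lengths
  ttl_range = c(100, 600),    # cm, extant total lengths (cross-species)
  noise_svl = 0.03, noise_ttl = 0.03, noise_bm = 0.06, noise_bf = 0.06,
  n_svl = 30L, n_body = 23L   # ~ontogenetic series / all living species
)

#' Simulate the two crocodilian calibration panels
#'
#' Generates the pair of tables the estimation chain is calibrated on: an
#' ontogenetic-series panel (~30 records of DCL, SVL, TTL for a single
#' caiman species) and a cross-species panel (~23 records of TTL, BM, BF,
#' one per living crocodilian species). Responses follow the published
#' power-law coefficients with lognormal scatter; predictor ranges cover
#' extant animals only. These are statistical stand-ins with the structure
#' the analysis assumes, not reconstructions of any real measurement set.
#'
#' @param seed integer seed.
#' @param n_svl,n_body panel sizes.
#' @param noise_sd optional single log10 noise sd applied to all four
#'   relationships, overriding the per-relationship defaults.
#' @param missing_rate fraction of measurement cells blanked at random
#'   (never leaving a record empty), default 0.
#' @return List with elements `svl_table` and `body_table`, both
#'   [calibration_table()]s, plus `params` recording the generating values.
#' @export
#' @examples
#' panel <- simulate_crocodilian_panel(seed = 42)
#' nrow(panel$body_table)
simulate_crocodilian_panel <- function(seed = 20150217L,
                                       n_svl = .panel_defaults$n_svl,
                                       n_body = .panel_defaults$n_body,
                                       noise_sd = NULL,
                                       missing_rate = 0) {
  d <- .panel_defaults
  pc <- .published_coefs
  ns <- if (is.null(noise_sd)) {
    c(d$noise_svl, d$noise_ttl, d$noise_bm, d$noise_bf)
  } else rep_len(noise_sd, 4L)

  set.seed(as.integer(seed %% .Machine$integer.max))
  # ontogenetic panel: dcl drawn log-uniformly, svl from dcl, ttl from svl
  l_dcl <- stats::runif(n_svl, log10(d$dcl_range[1L]), log10(d$dcl_range[2L]))
  l_svl <- pc$a[1L] + pc$b[1L] * l_dcl + stats::rnorm(n_svl, 0, ns[1L])
  l_ttl <- pc$a[2L] + pc$b[2L] * l_svl + stats::rnorm(n_svl, 0, ns[2L])
  svl_table <- calibration_table(
    specimen_id = sprintf("cl%02d", seq_len(n_svl)),
    species = "Caiman latirostris",
    dcl = 10^l_dcl, svl = 10^l_svl, ttl = 10^l_ttl,
    source_label = "synthetic ontogenetic panel"
  )
  # cross-species panel: ttl drawn log-uniformly, bm from ttl, bf from bm
  l_ttl2 <- stats::runif(n_body, log10(d$ttl_range[1L]), log10(d$ttl_range[2L]))
  l_bm <- pc$a[3L] + pc$b[3L] * l_ttl2 + stats::rnorm(n_body, 0, ns[3L])
  l_bf <- pc$a[4L] + pc$b[4L] * l_bm + stats::rnorm(n_body, 0, ns[4L])
  body_table <- calibration_table(
    specimen_id = sprintf("sp%02d", seq_len(n_body)),
    species = sprintf("Crocodylia sp. %02d", seq_len(n_body)),
    ttl = 10^l_ttl2, bm = 10^l_bm, bf = 10^l_bf,
    source_label = "synthetic cross-species panel"
  )

  if (missing_rate > 0) {
    svl_table <- blank_cells(svl_table, c("dcl", "svl", "ttl"), missing_rate)
    body_table <- blank_cells(body_table, c("ttl", "bm", "bf"), missing_rate)
  }
  list(
    svl_table = svl_table,
    body_table = body_table,
    params = list(seed = seed, n_svl = n_svl, n_body = n_body, noise_sd = ns,
                  coefficients = pc[, c("stage", "a", "b")],
                  dcl_range = d$dcl_range, ttl_range = d$ttl_range,
                  missing_rate = missing_rate)
  )
}

# Blank measurement cells at random without ever emptying a record.
blank_cells <- function(table, roles, rate) {
  for (role in roles) {
    drop <- stats::runif(nrow(table)) < rate
    # keep at least one measurement per record
    others <- setdiff(roles, role)
    has_other <- rowSums(!is.na(as.matrix(as.data.frame(table)[others]))) > 0
    table[[role]][drop & has_other] <- NA_real_
  }
  validate_calibration_table(table)
}

#' Write simulated panels to disk
#'
#' Writes the two calibration CSVs plus a JSON sidecar recording the
#' generating parameters, for use as on-disk fixtures.
#'
#' @param panel result of [simulate_crocodilian_panel()].
#' @param dir output directory (created if needed).
#' @return Character vector of the three paths written, invisibly.
#' @export
write_panel_fixtures <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    svl = file.path(dir, "svl_panel.csv"),
    body = file.path(dir, "body_panel.csv"),
    params = file.path(dir, "panel_params.json")
  )
  write_calibration(panel$svl_table, paths[["svl"]])
  write_calibration(panel$body_table, paths[["body"]])
  jsonlite::write_json(panel$params, paths[["params"]],
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}
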