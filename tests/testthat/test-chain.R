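test_that("the published chain embeds the reference coefficient set, fully linked", {
  chain <- published_chain()
  expect_equal(chain$bm_model$a, -5.1240)
  expect_equal(chain$bm_model$b, 2.9221)
  expect_equal(chain$ttl_model$a, 0.41689)
  expect_equal(chain$ttl_model$b, 0.91905)
  expect_equal(chain$svl_model$r, 0.9844)
  expect_equal(chain$bf_model$b_ci, c(0.55584, 0.77968))
  models <- list(chain$svl_model, chain$ttl_model, chain$bm_model,
                 chain$bf_model)
  for (i in 1:3) {
    expect_identical(models[[i]]$y_role, models[[i + 1]]$x_role)
  }
  expect_identical(chain$provenance, "published")
})

test_that("the published chain reproduces the reference estimates at DCL 1400 mm", {
  res <- estimate_from_dcl(1400, published_chain())
  expect_equal(res$svl$point, 824.2, tolerance = 0.005)
  expect_equal(res$ttl$point, 1249.9, tolerance = 0.005)
  expect_equal(res$bm$point, 8423.9, tolerance = 0.005)
  expect_equal(res$bf$point, 69039.2, tolerance = 0.005)
  expect_false(res$limits_available)
  expect_true(is.na(res$svl$lower))
})

test_that("an identity chain passes the input through unchanged", {
  ident <- function(x_role, y_role) {
    published_model(a = 0, b = 1, x_role = x_role, y_role = y_role)
  }
  chain <- structure(list(
    svl_model = ident("dcl", "svl"), ttl_model = ident("svl", "ttl"),
    bm_model = ident("ttl", "bm"), bf_model = ident("bm", "bf"),
    provenance = "published"), class = "model_chain")
  res <- estimate_from_dcl(137.5, chain)
  expect_equal(res$svl$point, 137.5)
  expect_equal(res$ttl$point, 137.5)
  expect_equal(res$bm$point, 137.5)
  expect_equal(res$bf$point, 137.5)
})

test_that("chained estimation equals manual stage-by-stage composition", {
  set.seed(99)
  for (trial in 1:5) {
    coefs <- list(a = runif(4, -2, 2), b = runif(4, 0.3, 2))
    roles <- list(c("dcl", "svl"), c("svl", "ttl"), c("ttl", "bm"),
                  c("bm", "bf"))
    models <- lapply(1:4, function(i) {
      published_model(a = coefs$a[i], b = coefs$b[i],
                      x_role = roles[[i]][1], y_role = roles[[i]][2])
    })
    chain <- structure(list(svl_model = models[[1]], ttl_model = models[[2]],
                            bm_model = models[[3]], bf_model = models[[4]],
                            provenance = "published"), class = "model_chain")
    dcl <- 10^runif(1, 2, 3.5)
    res <- estimate_from_dcl(dcl, chain)
    manual <- predict_point(models[[4]],
                predict_point(models[[3]],
                  predict_point(models[[2]],
                    predict_point(models[[1]], dcl))))
    expect_identical(res$bf$point, manual)
  }
})

test_that("chain estimates are monotone in DCL when all slopes are positive", {
  chain <- published_chain()
  res_small <- estimate_from_dcl(900, chain)
  res_large <- estimate_from_dcl(1400, chain)
  for (stage in c("svl", "ttl", "bm", "bf")) {
    expect_lt(res_small[[stage]]$point, res_large[[stage]]$point)
  }
})

test_that("broken linkage and invalid inputs are rejected", {
  chain <- published_chain()
  chain$ttl_model$x_role <- "dcl"
  expect_error(estimate_from_dcl(1400, chain), "linkage|not linked",
               class = "crocallometry_validation")
  expect_error(estimate_from_dcl(-5, published_chain()), "positive")
})

test_that("noiseless synthetic panels recover the generating chain almost exactly", {
  panel <- simulate_crocodilian_panel(seed = 303, noise_sd = 0)
  chain <- fit_chain(panel$svl_table, panel$body_table,
                     bootstrap_config(n_reps = 50, seed = 1))
  ref <- ref_coefs()
  fitted_models <- list(chain$svl_model, chain$ttl_model, chain$bm_model,
                        chain$bf_model)
  for (i in 1:4) {
    expect_equal(fitted_models[[i]]$a, ref$a[i], tolerance = 1e-8)
    expect_equal(fitted_models[[i]]$b, ref$b[i], tolerance = 1e-8)
  }
  expect_identical(chain$provenance, "fitted")
})

test_that("a fitted chain yields log-symmetric per-stage limits and is seed-stable", {
  panel <- simulate_crocodilian_panel(seed = 7)
  cfg <- bootstrap_config(n_reps = 300, seed = 11)
  chain <- fit_chain(panel$svl_table, panel$body_table, cfg)
  res <- estimate_from_dcl(1400, chain)
  expect_true(res$limits_available)
  for (stage in c("svl", "ttl", "bm", "bf")) {
    s <- res[[stage]]
    expect_true(0 < s$lower && s$lower <= s$point && s$point <= s$upper)
    expect_equal(s$upper / s$point, s$point / s$lower, tolerance = 1e-12)
  }
  # limits evaluated at each stage's incoming point, so each stage's point
  # must equal the previous stage's point fed forward
  expect_identical(res$ttl$x0, res$svl$point)
  expect_identical(res$bf$x0, res$bm$point)

  chain2 <- fit_chain(panel$svl_table, panel$body_table, cfg)
  res2 <- estimate_from_dcl(1400, chain2)
  expect_identical(res, res2)
})

test_that("stage failures name the failing stage", {
  panel <- simulate_crocodilian_panel(seed = 5)
  crippled <- panel$body_table
  crippled$bf[4:nrow(crippled)] <- NA   # leaves < 3 (bm, bf) pairs? keep 3
  crippled$bf[1:2] <- NA                 # now only 1 complete pair
  expect_error(
    fit_chain(panel$svl_table, crippled, bootstrap_config(n_reps = 10, seed = 1)),
    "stage 4.*bm -> bf", class = "crocallometry_validation")
})

test_that("Monte-Carlo propagation widens the downstream limits it accumulates", {
  panel <- simulate_crocodilian_panel(seed = 29)
  cfg <- bootstrap_config(n_reps = 500, seed = 17)
  chain <- fit_chain(panel$svl_table, panel$body_table, cfg)
  res <- estimate_from_dcl(1400, chain)
  mc <- chain_mc_intervals(chain, 1400, n_draws = 4000, seed = 55)
  # same point estimates
  for (stage in c("svl", "ttl", "bm", "bf")) {
    expect_equal(mc$stages[[stage]]$point, res[[stage]]$point, tolerance = 1e-12)
  }
  # accumulated uncertainty: the final-stage MC interval is wider on the log
  # scale than the per-regression limit
  width_mc <- log10(mc$stages$bf$upper / mc$stages$bf$lower)
  width_pr <- log10(res$bf$upper / res$bf$lower)
  expect_gt(width_mc, width_pr)
  # deterministic per seed
  mc2 <- chain_mc_intervals(chain, 1400, n_draws = 4000, seed = 55)
  expect_identical(mc, mc2)
  # refuses chains without replicates
  expect_error(chain_mc_intervals(published_chain(), 1400),
               "bootstrap replicates", class = "crocallometry_validation")
})
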