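test_that("exact power-law data are recovered exactly", {
  pairs <- data.frame(x = c(1, 10, 100), y = 10^0.5 * c(1, 10, 100)^2)
  m <- fit_loglog(pairs)
  expect_equal(m$a, 0.5, tolerance = 1e-12)
  expect_equal(m$b, 2, tolerance = 1e-12)
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_equal(m$residual_sd, 0, tolerance = 1e-12)

  flat <- fit_loglog(data.frame(x = c(1, 10, 100), y = c(1, 1, 1)))
  expect_equal(flat$a, 0, tolerance = 1e-12)
  expect_equal(flat$b, 0, tolerance = 1e-12)
})

test_that("fitted coefficients match the normal-equations oracle on noisy panels", {
  pairs <- make_powerlaw_pairs(200, a = -5.1240, b = 2.9221, noise_sd = 0.05,
                               x_range = c(100, 600), seed = 42)
  m <- fit_loglog(pairs)
  oracle <- oracle_normal_equations(pairs)
  # 10 significant digits
  expect_equal(m$a, unname(oracle["a"]), tolerance = 1e-10)
  expect_equal(m$b, unname(oracle["b"]), tolerance = 1e-10)

  # analytic sampling error of the slope at this design, from first principles
  u <- log10(pairs$x)
  se_b <- 0.05 / sqrt(sum((u - mean(u))^2))
  expect_lt(abs(m$b - 2.9221), 3 * se_b)
  se_a <- 0.05 * sqrt(1 / 200 + mean(u)^2 / sum((u - mean(u))^2))
  expect_lt(abs(m$a - (-5.1240)), 3 * se_a)
})

test_that("preconditions are enforced: positivity, sample size, constant predictor", {
  expect_error(fit_loglog(data.frame(x = c(1, 2), y = c(1, 2))), "at least 3")
  expect_error(fit_loglog(data.frame(x = c(1, -2, 3), y = c(1, 2, 3))),
               "strictly positive")
  expect_error(fit_loglog(data.frame(x = c(2, 2, 2), y = c(1, 2, 3))),
               "constant predictor")
})

test_that("pearson_r matches hand-computed correlation and its exact limits", {
  up <- data.frame(x = c(2, 20, 200, 2000), y = 3 * c(2, 20, 200, 2000)^1.7)
  expect_equal(pearson_r(up), 1, tolerance = 1e-12)

  down <- data.frame(x = c(1, 2, 5, 10), y = 10 / c(1, 2, 5, 10))
  expect_equal(pearson_r(down), -1, tolerance = 1e-12)

  noisy <- make_powerlaw_pairs(60, a = 0.4, b = 0.9, noise_sd = 0.08, seed = 9)
  expect_equal(pearson_r(noisy),
               oracle_pearson(log10(noisy$x), log10(noisy$y)),
               tolerance = 1e-12)
  expect_error(pearson_r(data.frame(x = 1:3, y = c(5, 5, 5))),
               "constant variate")
})

test_that("r squared equals the coefficient of determination of the log fit", {
  for (seed in c(2, 71, 828)) {
    pairs <- make_powerlaw_pairs(40, a = 1.1, b = 0.7, noise_sd = 0.1,
                                 seed = seed)
    m <- fit_loglog(pairs)
    v <- log10(pairs$y)
    fitted <- m$a + m$b * log10(pairs$x)
    r2 <- 1 - sum((v - fitted)^2) / sum((v - mean(v))^2)
    expect_equal(m$r^2, r2, tolerance = 1e-10)
  }
})

test_that("rescaling x shifts the intercept by -b log10(c) and preserves b and r", {
  pairs <- make_powerlaw_pairs(35, a = -0.5, b = 1.1, noise_sd = 0.04, seed = 5)
  m <- fit_loglog(pairs)
  for (c_fac in c(10, 0.1, 2.54)) {
    scaled <- data.frame(x = pairs$x * c_fac, y = pairs$y)
    ms <- fit_loglog(scaled)
    expect_equal(ms$b, m$b, tolerance = 1e-10)
    expect_equal(ms$r, m$r, tolerance = 1e-10)
    expect_equal(ms$a, m$a - m$b * log10(c_fac), tolerance = 1e-10)
  }
})

test_that("predict_point back-transforms the published equations correctly", {
  svl <- published_model(a = -0.56913, b = 1.10776)
  expect_equal(predict_point(svl, 1400), 824.2, tolerance = 0.005)

  bf <- published_model(a = 2.21779, b = 0.66776)
  expect_equal(predict_point(bf, 8423.9), 69039.2, tolerance = 0.005)

  ident <- published_model(a = 0, b = 1)
  expect_equal(predict_point(ident, 55), 55, tolerance = 1e-12)
  expect_error(predict_point(ident, -1), "positive")
})

test_that("predict_point is monotone in x0 with the sign of the slope", {
  xs <- 10^seq(0, 3, length.out = 20)
  up <- published_model(a = -1, b = 0.8)
  down <- published_model(a = 2, b = -0.6)
  expect_true(all(diff(vapply(xs, function(x) predict_point(up, x),
                              numeric(1))) > 0))
  expect_true(all(diff(vapply(xs, function(x) predict_point(down, x),
                              numeric(1))) < 0))
})
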