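test_that("noiseless 4PL data returns its generating parameters", {
  cases <- list(
    list(e_min = 0, e_max = 1, m = 10, lambda = 1),
    list(e_min = 0.05, e_max = 0.9, m = 0.3, lambda = 2.5),
    list(e_min = 0, e_max = 0.7, m = 120, lambda = 0.6),
    list(e_min = 0.1, e_max = 1, m = 5, lambda = 4))
  for (p in cases) {
    doses <- c(0, p$m * 10^seq(-2, 2, length.out = 7))
    eff <- fourpl_effect(doses, p$e_min, p$e_max, p$m, p$lambda)
    crv <- fit_dose_response(doses, eff)
    expect_equal(crv$kind, "4pl")
    expect_lt(abs(crv$params$m - p$m) / p$m, 1e-4)
    expect_lt(abs(crv$params$lambda - p$lambda) / p$lambda, 1e-4)
  }
})

test_that("4PL prediction honours its closed-form landmarks", {
  crv <- exact_curve(e_min = 0, e_max = 1, m = 10, lambda = 1)
  expect_equal(predict_effect(crv, 10), 0.5)
  expect_equal(predict_effect(crv, 0), 0)
  crv2 <- exact_curve(e_min = 0.1, e_max = 0.9, m = 4, lambda = 2)
  expect_equal(predict_effect(crv2, 0), 0.1)
  # lambda = 2, dose = m*sqrt(3): (x/m)^2 = 3 -> 3/4 of the effect window
  expect_equal(predict_effect(crv2, 4 * sqrt(3)), 0.1 + 0.75 * 0.8)
})

test_that("constant responses give a flat linear fit", {
  crv <- fit_dose_response(c(0, 1, 10, 100), rep(0.5, 4), model = "linear")
  expect_equal(crv$params$slope, 0, tolerance = 1e-12)
  expect_equal(crv$params$intercept, 0.5)
})

test_that("fewer than two distinct nonzero doses is insufficient data", {
  expect_error(fit_dose_response(c(0, 5), c(0, 0.6)),
               class = "combosyn_insufficient_data")
  expect_error(fit_dose_response(c(0, 5, 5), c(0, 0.5, 0.7), model = "linear"),
               class = "combosyn_insufficient_data")
})

test_that("inverse_dose inverts the curve and flags unreachable effects", {
  crv <- exact_curve(e_min = 0, e_max = 1, m = 10, lambda = 1)
  expect_equal(inverse_dose(crv, 0.5), 10)
  expect_true(is.na(inverse_dose(crv, 1.2)))
  expect_true(is.na(inverse_dose(exact_curve(e_max = 0.8), 0.9)))
  set.seed(42)
  for (i in 1:10) {
    crv_i <- exact_curve(e_min = runif(1, 0, 0.1), e_max = runif(1, 0.6, 1),
                         m = 10^runif(1, -1, 2), lambda = runif(1, 0.3, 5))
    y <- runif(5, crv_i$params$e_min + 1e-3, crv_i$params$e_max - 1e-3)
    expect_lt(max(abs(predict_effect(crv_i, inverse_dose(crv_i, y)) - y)), 1e-8)
  }
})

test_that("4PL prediction is monotone in dose for positive slope", {
  crv <- exact_curve(e_min = 0.02, e_max = 0.95, m = 3, lambda = 1.7)
  grid <- c(0, 10^seq(-3, 3, length.out = 200))
  expect_true(all(diff(predict_effect(crv, grid)) >= 0))
})

test_that("fitting is invariant to point order, duplication, and replicate pooling", {
  doses <- c(0, 0.1, 1, 10, 100)
  eff <- fourpl_effect(doses, 0, 1, 5, 1.2) + c(0.01, -0.02, 0.015, 0, -0.01)
  base <- fit_dose_response(doses, eff)
  shuf <- fit_dose_response(rev(doses), rev(eff))
  expect_equal(shuf$params, base$params, tolerance = 1e-6)
  dup <- fit_dose_response(c(doses, doses), c(eff, eff))
  expect_equal(dup$params, base$params, tolerance = 1e-4)
  rep2 <- eff + 0.02
  pooled <- fit_dose_response(doses, eff, replicate_effects = list(rep2))
  concat <- fit_dose_response(c(doses, doses), c(eff, rep2))
  expect_equal(pooled$params, concat$params)
})

test_that("LOESS fits smooth monotone data and refuses non-monotone inversion", {
  doses <- c(0, 10^seq(-1, 2, length.out = 10))
  eff <- fourpl_effect(doses, 0, 1, 3, 1.5)
  crv <- fit_dose_response(doses, eff, model = "loess")
  expect_equal(predict_effect(crv, 3), fourpl_effect(3, 0, 1, 3, 1.5),
               tolerance = 0.05)
  d <- inverse_dose(crv, 0.5)
  expect_equal(predict_effect(crv, d), 0.5, tolerance = 1e-6)
  # U-shaped response: effect falls back at high dose
  u_eff <- c(0, 0.05, 0.2, 0.45, 0.7, 0.85, 0.9, 0.8, 0.55, 0.3, 0.1)
  crv_u <- suppressWarnings(
    fit_dose_response(doses, u_eff, model = "loess", span = 0.5))
  expect_error(inverse_dose(crv_u, 0.6), class = "combosyn_not_invertible")
})
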