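test_that("HSA score is the excess over the best single agent", {
  expect_equal(hsa_score(0.8, c(0.5, 0.6)), 0.2)
  expect_equal(hsa_score(0.5, c(0.5, 0.3, 0.2)), 0)
  set.seed(1)
  e <- runif(4)
  expect_equal(hsa_score(0.7, e), hsa_score(0.7, sample(e)))
  expect_error(hsa_score(0.5, numeric(0)))
})

test_that("Bliss expectation equals the expanded inclusion-exclusion sum", {
  expect_equal(bliss_score(0.875, c(0.5, 0.5, 0.5)), 0)
  expect_equal(bliss_score(0.5, c(0.2, 0.3)), 0.06)
  set.seed(7)
  for (n in 2:5) {
    e <- runif(n)
    expect_equal(bliss_expected(e), union_by_expansion(e), tolerance = 1e-12)
  }
  # singles outside [0,1] are clamped inside the product only
  expect_equal(bliss_expected(c(1.05, 0.5)), 1)
  expect_lte(bliss_expected(c(-0.1, 0.4)), 1)
})

test_that("Bliss expectation stays within [0,1] for probability-like singles", {
  set.seed(3)
  for (i in 1:50) {
    e <- runif(sample(2:5, 1))
    b <- bliss_expected(e)
    expect_gte(b, 0); expect_lte(b, 1)
  }
})

test_that("ZIP expectation multiplies fitted logistic potency terms", {
  c1 <- exact_curve(m = 2, lambda = 1.5)
  c2 <- exact_curve(m = 8, lambda = 0.8)
  expect_equal(zip_expected(c(2, 8), list(c1, c2)), 0.75)
  # dose 0 contributes p = 0
  expect_equal(zip_expected(c(0, 8), list(c1, c2)), 0.5)
  # product form equals the expanded sum for three drugs
  c3 <- exact_curve(m = 0.5, lambda = 3)
  doses <- c(1.3, 11, 0.4)
  p <- vapply(seq_len(3), function(i) {
    crv <- list(c1, c2, c3)[[i]]
    t <- (doses[i] / crv$params$m)^crv$params$lambda
    t / (1 + t)
  }, numeric(1))
  expect_equal(zip_expected(doses, list(c1, c2, c3)), union_by_expansion(p),
               tolerance = 1e-12)
  # asymptotes do not enter the printed ZIP term
  shifted <- exact_curve(e_min = 0, e_max = 0.6, m = 2, lambda = 1.5)
  expect_equal(zip_expected(c(2, 8), list(shifted, c2)), 0.75)
  expect_error(zip_expected(1, list(fit_dose_response(c(0, 1, 10), c(0, 0.3, 0.6),
                                                      model = "linear"))),
               class = "combosyn_model_unavailable")
})

test_that("Loewe reproduces the sham combination and the dense-grid root", {
  crv <- exact_curve(e_min = 0, e_max = 1, m = 10, lambda = 1.3)
  for (d in c(2, 10, 40)) {
    expect_equal(loewe_expected(c(d / 2, d / 2), list(crv, crv)),
                 predict_effect(crv, d), tolerance = 1e-6)
  }
  # grid-search oracle on random curve pairs
  set.seed(5)
  for (i in 1:5) {
    curves <- lapply(1:2, function(j) {
      exact_curve(e_min = 0, e_max = runif(1, 0.7, 1),
                  m = 10^runif(1, -0.5, 1.5), lambda = runif(1, 0.7, 3))
    })
    doses <- vapply(curves, function(cv) cv$params$m * 10^runif(1, -0.5, 0.5),
                    numeric(1))
    y_hat <- loewe_expected(doses, curves)
    y_lo <- max(vapply(curves, function(cv) cv$params$e_min, numeric(1)))
    y_hi <- max(vapply(curves, function(cv) cv$params$e_max, numeric(1)))
    grid <- seq(y_lo + 1e-9, y_hi - 1e-9, length.out = 200001)
    total <- rowSums(vapply(seq_along(curves), function(j) {
      D <- inverse_dose(curves[[j]], grid)
      r <- doses[j] / D
      r[is.na(D)] <- 0
      r
    }, numeric(length(grid))))
    y_grid <- grid[which.min(abs(total - 1))]
    expect_lt(abs(y_hat - y_grid), 1e-5)
  }
  # one dose vanishing: expectation tends to the other drug's monotherapy
  c2 <- exact_curve(e_min = 0, e_max = 0.9, m = 4, lambda = 2)
  y <- loewe_expected(c(1e-9 * crv$params$m, 5), list(crv, c2))
  expect_equal(y, predict_effect(c2, 5), tolerance = 1e-4)
})

test_that("effects beyond a weak agent's reach contribute zero dose-ratio to Loewe", {
  strong <- exact_curve(e_min = 0, e_max = 1, m = 1, lambda = 1)
  weak <- exact_curve(e_min = 0, e_max = 0.3, m = 1, lambda = 1)
  # the solution lies above the weak drug's asymptote, where only the strong
  # drug's dose-ratio counts: y solves d_s / D_s(y) = 1, i.e. y = f_s(d_s)
  y <- loewe_expected(c(9, 5), list(strong, weak))
  expect_gt(y, 0.3)
  expect_equal(y, predict_effect(strong, 9), tolerance = 1e-6)
})

test_that("sub-combination enumeration is complete and ordered", {
  expect_length(enumerate_subcombinations(c("A", "B")), 1)
  subs3 <- enumerate_subcombinations(c("A", "B", "C"))
  expect_length(subs3, 4)
  expect_equal(subs3[[1]], c("A", "B"))
  expect_equal(subs3[[4]], c("A", "B", "C"))
  expect_length(enumerate_subcombinations(LETTERS[1:4]), 11)
  expect_error(enumerate_subcombinations("A"))
})

test_that("a Bliss-additive tensor scores zero everywhere and recovers a planted offset", {
  null3 <- simulate_combo_block(fixture_spec(n_drugs = 3, seed = 8))$block
  res <- score_block(null3, models = "Bliss")
  expect_length(res$surfaces, 4)
  for (s in res$surfaces) expect_lt(max(abs(s$scores)), 1e-12)

  planted <- simulate_combo_block(fixture_spec(synergy_offset = 0.15,
                                               seed = 8))$block
  sm <- summarize_synergy(score_block(planted, models = "Bliss"))
  expect_equal(sm$summary_score, 0.15, tolerance = 1e-12)
})

test_that("scoring a subset inside a larger tensor equals scoring the extracted sub-tensor", {
  fx <- simulate_combo_block(fixture_spec(n_drugs = 3, noise_sd = 0.04,
                                          n_replicates = 2,
                                          synergy_offset = 0.1, seed = 13))
  full <- score_block(fx$block)
  sub2 <- combosyn:::slice_block(fx$block, c("A", "C"))
  alone <- score_block(sub2)
  for (model in c("HSA", "Bliss", "Loewe", "ZIP")) {
    inside <- full$surfaces[[paste0("A+C|", model)]]
    outside <- alone$surfaces[[paste0("A+C|", model)]]
    expect_equal(inside$scores, outside$scores, tolerance = 1e-12)
  }
})

test_that("scores are invariant under permutation of drug labels", {
  fx <- simulate_combo_block(fixture_spec(
    n_drugs = 3,
    curves = list(list(e_min = 0, e_max = 1, m = 1, lambda = 1),
                  list(e_min = 0, e_max = 0.8, m = 3, lambda = 2),
                  list(e_min = 0, e_max = 0.9, m = 0.5, lambda = 0.7)),
    synergy_offset = 0.05, seed = 21))
  blk <- fx$block
  # rebuild the same block with drug axes swapped (B, C, A)
  w <- blk$wells
  w2 <- tibble::tibble(conc_1 = w$conc_2, conc_2 = w$conc_3, conc_3 = w$conc_1,
                       effect = w$effect, replicate = w$replicate)
  blk2 <- combosyn:::new_combo_block("perm", c("B", "C", "A"), w2)
  r1 <- summarize_synergy(score_block(blk))
  r2 <- summarize_synergy(score_block(blk2))
  key <- function(tb) {
    tb$subset_sorted <- vapply(strsplit(tb$drug_subset, "+", fixed = TRUE),
                               function(x) paste(sort(x), collapse = "+"),
                               character(1))
    tb[order(tb$subset_sorted, tb$model), c("subset_sorted", "model", "summary_score")]
  }
  expect_equal(key(r2)$summary_score, key(r1)$summary_score, tolerance = 1e-9)
})

test_that("summaries average unmasked wells and track replicate spread", {
  fx <- simulate_combo_block(fixture_spec(noise_sd = 0.05, n_replicates = 3,
                                          synergy_offset = 0.1, seed = 17))
  res <- score_block(fx$block, models = "Bliss")
  surf <- res$surfaces[[1]]
  sm <- summarize_surface(surf)
  expect_equal(sm$summary_score, mean(surf$scores))
  expect_equal(sm$n_wells, length(surf$scores))
  # SD equals the spread of the per-replicate summary means, computed directly
  rep_means <- colMeans(surf$replicate_scores)
  expect_equal(sm$sd, sd(rep_means))
  # masking the middle wells changes the mean accordingly
  surf$mask[c(2, 3)] <- TRUE
  sm2 <- summarize_surface(surf)
  expect_equal(sm2$summary_score, mean(surf$scores[-c(2, 3)]))
  expect_equal(sm2$n_wells, length(surf$scores) - 2L)
  surf$mask[] <- TRUE
  expect_error(summarize_surface(surf), class = "combosyn_empty_summary")
})

test_that("single-replicate wells report no replicate SD", {
  blk <- simulate_combo_block(fixture_spec(seed = 2))$block
  sm <- summarize_synergy(score_block(blk, models = "HSA"))
  expect_true(is.na(sm$sd))
})

test_that("partial designs score HSA and Bliss but refuse Loewe and ZIP", {
  blk <- partial_block()
  expect_equal(block_design(blk), "partial")
  res <- score_block(blk, models = c("HSA", "Bliss"))
  tb <- tidy(res)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$score[tb$model == "HSA"], 0.8 - 0.4)
  expect_equal(tb$score[tb$model == "Bliss"], 0.8 - (0.3 + 0.4 - 0.12))
  expect_error(score_block(blk, models = "Loewe"),
               "Bliss and HSA", class = "combosyn_design_error")
  expect_error(score_block(blk, models = "ZIP"),
               class = "combosyn_design_error")
})
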