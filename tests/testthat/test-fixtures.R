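test_that("each null generator is exactly null under its matching score", {
  # Bliss null -> Bliss scores at machine zero
  b <- simulate_combo_block(fixture_spec(null_model = "Bliss", seed = 1))$block
  s <- score_block(b, models = "Bliss")$surfaces[[1]]
  expect_lt(max(abs(s$scores)), 1e-12)
  # HSA null -> HSA scores at machine zero
  h <- simulate_combo_block(fixture_spec(null_model = "HSA", seed = 1))$block
  s <- score_block(h, models = "HSA")$surfaces[[1]]
  expect_lt(max(abs(s$scores)), 1e-12)
  # sham combination -> Loewe scores ~0 (solver tolerance)
  sham <- simulate_combo_block(fixture_spec(null_model = "Loewe-sham",
                                            seed = 1))$block
  s <- score_block(sham, models = "Loewe")$surfaces[[1]]
  expect_lt(max(abs(s$scores)), 1e-6)
  # ZIP null with 0/1 asymptotes -> ZIP ~0 up to curve-fit error
  z <- simulate_combo_block(fixture_spec(null_model = "ZIP", seed = 1))$block
  s <- score_block(z, models = "ZIP")$surfaces[[1]]
  expect_lt(max(abs(s$scores)), 1e-3)
})

test_that("a planted offset is recovered exactly without noise", {
  fx <- simulate_combo_block(fixture_spec(n_drugs = 3, synergy_offset = 0.15,
                                          seed = 5))
  sm <- summarize_synergy(score_block(fx$block, models = "Bliss"))
  expect_equal(sm$summary_score[sm$drug_subset == "A+B+C"], 0.15,
               tolerance = 1e-12)
  # pairs see no offset (it lives on the full interior only)
  expect_lt(max(abs(sm$summary_score[sm$subset_size == 2])), 1e-12)
})

test_that("region-restricted offsets only touch the selected wells", {
  fx <- simulate_combo_block(fixture_spec(
    synergy_offset = 0.2,
    offset_region = function(d) all(d >= 1), seed = 5))
  s <- score_block(fx$block, models = "Bliss")$surfaces[[1]]
  tb <- tidy(s)
  hit <- tb$conc_1 >= 1 & tb$conc_2 >= 1
  expect_equal(tb$score[hit], rep(0.2, sum(hit)), tolerance = 1e-12)
  expect_lt(max(abs(tb$score[!hit])), 1e-12)
})

test_that("generation is reproducible and noise respects the truncation bounds", {
  spec <- fixture_spec(noise_sd = 0.5, n_replicates = 4, seed = 99)
  b1 <- simulate_combo_block(spec)$block
  b2 <- simulate_combo_block(spec)$block
  expect_identical(b1$wells, b2$wells)
  expect_gte(min(b1$wells$effect), -0.2)
  expect_lte(max(b1$wells$effect), 1.2)
})

test_that("written fixture files round-trip through the matching reader", {
  for (n in 2:3) {
    fx <- simulate_combo_block(fixture_spec(n_drugs = n, noise_sd = 0.03,
                                            n_replicates = 2, seed = n))
    f <- tempfile(fileext = ".csv")
    write_combo_file(fx$block, f, dialect = "table")
    back <- suppressWarnings(read_combo_table(f)[[1]])
    expect_equal(replicate_array(back), replicate_array(fx$block))
  }
  fx2 <- simulate_combo_block(fixture_spec(seed = 12))
  fm <- tempfile(fileext = ".tsv")
  write_combo_file(fx2$block, fm, dialect = "matrix")
  expect_equal(response_array(read_combo_matrix(fm)[[1]]),
               response_array(fx2$block))
  fx3 <- simulate_combo_block(fixture_spec(n_drugs = 3, seed = 12))
  expect_error(write_combo_file(fx3$block, fm, dialect = "matrix"),
               "table dialect", class = "combosyn_fixture_error")
})

test_that("fixture specs validate their own consistency", {
  expect_error(fixture_spec(
    null_model = "Loewe-sham",
    curves = list(list(e_min = 0, e_max = 1, m = 1, lambda = 1),
                  list(e_min = 0, e_max = 1, m = 2, lambda = 1))),
    class = "combosyn_fixture_error")
  expect_error(fixture_spec(curves = list(
    list(e_min = 0.1, e_max = 1, m = 1, lambda = 1),
    list(e_min = 0, e_max = 1, m = 1, lambda = 1))), "e_min")
  expect_error(fixture_spec(n_drugs = 1))
  expect_error(fixture_spec(dose_ladders = list(c(1, 10), c(0, 1, 10))),
               "dose 0")
})
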