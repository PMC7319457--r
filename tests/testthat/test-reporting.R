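make_scored_3drug <- function() {
  fx <- simulate_combo_block(fixture_spec(n_drugs = 3, noise_sd = 0.03,
                                          n_replicates = 2,
                                          synergy_offset = 0.1, seed = 41))
  score_block(fx$block)
}

test_that("exported landscape grids equal the surface scores cell-by-cell", {
  res <- make_scored_3drug()
  for (surf in res$surfaces[1:4]) {
    grid <- landscape_grid(surf)
    expect_equal(grid$score, surf$scores)
    expect_equal(grid$conc_1, surf$doses[[1]][surf$grid[, 1]])
  }
})

test_that("pair landscapes facet by the remaining drugs' doses", {
  res <- make_scored_3drug()
  surf3 <- res$surfaces[["A+B+C|Bliss"]]
  p <- plot_pair_landscape(surf3)
  expect_s3_class(p, "ggplot")
  expect_s3_class(p$facet, "FacetWrap")
  # one facet per nonzero dose of drug C
  built <- ggplot2::ggplot_build(p)
  n_facets <- length(unique(built$layout$layout$PANEL))
  expect_equal(n_facets, sum(res$block$doses[["C"]] > 0))
  # a plain pair has no facets
  p2 <- plot_pair_landscape(res$surfaces[["A+B|Bliss"]])
  expect_s3_class(p2$facet, "FacetNull")
})

test_that("an all-zero surface renders without error and exports zeros", {
  blk <- simulate_combo_block(fixture_spec(seed = 2))$block
  surf <- score_block(blk, models = "Bliss")$surfaces[[1]]
  expect_lt(max(abs(surf$scores)), 1e-12)
  expect_s3_class(plot_pair_landscape(surf), "ggplot")
  expect_true(all(abs(landscape_grid(surf)$score) < 1e-12))
})

test_that("barplot heights mirror the summary scores and drop absent error bars", {
  res <- make_scored_3drug()
  sm <- summarize_synergy(res)
  sm1 <- sm[sm$model == "Bliss", ]
  expect_equal(nrow(sm1), 4) # 3 pairs + 1 triplet
  p <- plot_subcombination_bars(sm1)
  built <- ggplot2::ggplot_build(p)
  bars <- built$data[[1]]
  heights <- ifelse(bars$ymax > 0, bars$ymax, bars$ymin)
  expect_equal(sort(heights), sort(sm1$summary_score))
  # without replicates there is no error-bar layer
  blk <- simulate_combo_block(fixture_spec(seed = 3))$block
  sm0 <- summarize_synergy(score_block(blk, models = "HSA"))
  p0 <- plot_subcombination_bars(sm0)
  expect_length(p0$layers, 1)
})

test_that("tensor slice views honour the tensor values and share colour limits", {
  ladders <- list(c(0, 1), c(0, 2), c(0, 4))
  fx <- simulate_combo_block(fixture_spec(n_drugs = 3, dose_ladders = ladders,
                                          seed = 9))
  p <- plot_tensor_slices(fx$block)
  df <- p$data
  expect_equal(length(unique(df$slice)), 2) # one per dose of C
  A <- response_array(fx$block)
  expect_equal(sort(df$response), sort(as.numeric(A)))
  lims <- p$scales$scales[[1]]$limits
  expect_equal(lims, range(A))
  expect_error(plot_tensor_slices(fx$block, drugs = c("A", "B")), "3 drugs")
})

test_that("reports embed their figures and ship a complete machine-readable bundle", {
  res <- make_scored_3drug()
  d <- withr::local_tempdir()
  out <- build_report(res, d, style = "short")
  expect_true(file.exists(out))
  html <- readLines(out)
  expect_true(any(grepl("data:image/png;base64", html)))

  d2 <- withr::local_tempdir()
  build_report(res, d2, style = "dynamic-data")
  csvs <- list.files(file.path(d2, "tables"))
  # per-well + summary tables plus one grid per surface
  expect_length(csvs, 2 + length(res$surfaces))

  # requested-but-unscored models are listed as unavailable, not fatal
  blk <- simulate_combo_block(fixture_spec(seed = 2))$block
  res_hsa <- score_block(blk, models = "HSA")
  out2 <- build_report(res_hsa, withr::local_tempdir(), style = "short",
                       models = c("HSA", "ZIP"))
  expect_true(any(grepl("Not available", readLines(out2))))
})

test_that("rebuilding a report reproduces its tables byte-identically", {
  blk <- simulate_combo_block(fixture_spec(noise_sd = 0.02, n_replicates = 2,
                                           seed = 15))$block
  res <- score_block(blk)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  build_report(res, d1, style = "dynamic-data")
  build_report(res, d2, style = "dynamic-data")
  for (f in list.files(file.path(d1, "tables"))) {
    expect_identical(readBin(file.path(d1, "tables", f), "raw", 1e7),
                     readBin(file.path(d2, "tables", f), "raw", 1e7))
  }
})
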