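#' Score a combination block under the reference models
#'
#' Computes dose-wise synergy surfaces for every sub-combination of >= 2
#' drugs in the block, under each requested reference model. For a subset
#' `S`, the surface covers the interior wells of `S`'s sub-tensor (all
#' subset doses > 0, all other drugs at dose 0); the score at each well is
#' the measured effect minus the model's expected effect.
#'
#' Monotherapy inputs for HSA and Bliss are the *measured* dose-0-elsewhere
#' wells (replicate means), so these two models also work on partial
#' designs. Loewe and ZIP need fitted monotherapy curves (multiple doses
#' per drug) and therefore refuse partial designs with a design-incompatible
#' error.
#'
#' With replicate measurements, curves are fitted on the pooled replicates
#' and each replicate is scored against the shared expected surface; the
#' per-well `replicate_sd` is the standard deviation of the replicate-wise
#' scores (absent for singly-measured wells).
#'
#' @param block A `combo_block`.
#' @param models Character vector among `"HSA"`, `"Bliss"`, `"Loewe"`,
#'   `"ZIP"` (case-insensitive).
#' @param curve_model Monotherapy curve family for Loewe/ZIP
#'   (see [fit_dose_response()]).
#' @param outlier_report Optional [detect_outliers()] result for this block;
#'   adds the per-well outlier flag to the surfaces.
#' @param exclude_outliers If `TRUE` (and a report is given), flagged wells
#'   are masked out of the summary averages.
#' @param span LOESS span when `curve_model = "loess"`.
#' @return A `synergy_result`: surfaces for all subsets x models, with
#'   `tidy()` (per-well scores) and [summarize_synergy()] support.
#' @examples
#' blk <- simulate_combo_block(fixture_spec(seed = 7))$block
#' res <- score_block(blk, models = c("HSA", "Bliss"))
#' summarize_synergy(res)
#' @export
score_block <- function(block, models = SYNERGY_MODELS,
                        curve_model = c("4pl", "linear", "loess"),
                        outlier_report = NULL, exclude_outliers = FALSE,
                        span = 0.75) {
  stopifnot(inherits(block, "combo_block"))
  models <- match_models(models)
  curve_model <- match.arg(curve_model)
  design <- block_design(block)
  if (design == "partial" && any(models %in% c("Loewe", "ZIP"))) {
    abort(paste0(
      "block ", block$block_id, " has a partial combination design: only the ",
      "Bliss and HSA synergy scores can be calculated, because Loewe and ZIP ",
      "require multiple doses per drug to fit monotherapy curves"),
      class = "combosyn_design_error")
  }
  curves <- if (any(models %in% c("Loewe", "ZIP"))) {
    fit_monotherapies(block, model = curve_model, span = span)
  } else NULL
  flags <- if (!is.null(outlier_report)) outlier_report$flags else NULL
  subsets <- enumerate_subcombinations(block$drugs)
  surfaces <- list()
  for (subset in subsets) {
    for (model in models) {
      surf <- score_subset(block, subset, model, curves, flags, exclude_outliers)
      surfaces[[paste(paste(subset, collapse = "+"), model, sep = "|")]] <- surf
    }
  }
  structure(list(block = block, models = models, curves = curves,
                 surfaces = surfaces, exclude_outliers = exclude_outliers,
                 design = design),
            class = "synergy_result")
}

# one synergy_surface: subset of drugs x one reference model
score_subset <- function(block, subset, model, curves, flags, exclude_outliers) {
  keep_k <- match(subset, block$drugs)
  sub <- slice_block(block, subset)
  A <- response_array(sub)
  R <- replicate_array(sub)
  nrep <- dim(R)[length(dim(R))]
  ns <- length(subset)
  pos_idx <- lapply(sub$doses, function(d) which(d > 0))
  pos_doses <- lapply(seq_len(ns), function(k) sub$doses[[k]][pos_idx[[k]]])
  names(pos_doses) <- subset
  idims <- lengths(pos_idx)
  # monotherapy replicate-mean effects at each drug's nonzero doses
  mono <- lapply(seq_len(ns), function(k) {
    idx <- as.matrix(expand.grid(lapply(seq_len(ns), function(j) {
      if (j == k) pos_idx[[k]] else which(sub$doses[[j]] == 0)
    })))
    A[idx]
  })
  grid <- as.matrix(expand.grid(lapply(idims, seq_len)))
  n_int <- nrow(grid)
  scores <- expected <- measured <- rep(NA_real_, n_int)
  ci_sum <- rep(NA_real_, n_int)
  rep_scores <- matrix(NA_real_, n_int, nrep)
  sub_curves <- if (!is.null(curves)) curves[subset] else NULL
  for (w in seq_len(n_int)) {
    gi <- grid[w, ]
    full_idx <- vapply(seq_len(ns), function(k) pos_idx[[k]][gi[k]], integer(1))
    meas <- A[matrix(full_idx, 1)]
    if (is.na(meas)) next
    doses_w <- vapply(seq_len(ns), function(k) pos_doses[[k]][gi[k]], numeric(1))
    singles <- vapply(seq_len(ns), function(k) mono[[k]][gi[k]], numeric(1))
    exp_w <- switch(model,
      HSA = max(singles),
      Bliss = bliss_expected(singles),
      Loewe = loewe_expected(doses_w, sub_curves),
      ZIP = zip_expected(doses_w, sub_curves))
    measured[w] <- meas
    expected[w] <- exp_w
    scores[w] <- meas - exp_w
    if (model == "Loewe") ci_sum[w] <- loewe_ci_sum(doses_w, sub_curves, meas)
    rep_vals <- R[cbind(matrix(full_idx, nrep, ns, byrow = TRUE), seq_len(nrep))]
    rep_scores[w, ] <- rep_vals - exp_w
  }
  n_meas_rep <- rowSums(!is.na(rep_scores))
  rep_sd <- ifelse(n_meas_rep >= 2,
                   apply(rep_scores, 1, stats::sd, na.rm = TRUE), NA_real_)
  flag_w <- rep(FALSE, n_int)
  if (!is.null(flags)) {
    other_zero <- vapply(seq_along(block$drugs), function(k) {
      which(block$doses[[k]] == 0)
    }, integer(1))
    for (w in seq_len(n_int)) {
      full <- other_zero
      for (j in seq_len(ns)) {
        k <- keep_k[j]
        full[k] <- match(pos_doses[[j]][grid[w, j]], block$doses[[k]])
      }
      flag_w[w] <- isTRUE(flags[matrix(full, 1)])
    }
  }
  structure(list(
    model = model, drugs = subset, doses = pos_doses,
    grid = grid, dims = idims,
    measured = measured, expected = expected, scores = scores,
    ci_sum = if (model == "Loewe") ci_sum else NULL,
    replicate_scores = rep_scores, replicate_sd = rep_sd,
    outlier_flag = flag_w,
    mask = flag_w & isTRUE(exclude_outliers),
    block_id = block$block_id
  ), class = "synergy_surface")
}

#' @export
print.synergy_surface <- function(x, ...) {
  cat("<synergy_surface> ", x$block_id, ": ", paste(x$drugs, collapse = "+"),
      " under ", x$model, "\n", sep = "")
  cat("  ", sum(!is.na(x$scores)), " interior wells, mean score ",
      sprintf("%.4f", mean(x$scores[!x$mask], na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("<synergy_result> block ", x$block$block_id, " (",
      paste(x$block$drugs, collapse = " + "), "), design = ", x$design,
      "\n  models: ", paste(x$models, collapse = ", "),
      "; ", length(x$surfaces), " surfaces\n", sep = "")
  invisible(x)
}

#' Per-well synergy scores as a tibble
#'
#' One row per interior well per drug subset per model: component doses,
#' measured and expected effects, synergy score, replicate SD, outlier flag,
#' and (for Loewe) the auxiliary combination-index sum at the measured
#' effect.
#'
#' @param x A `synergy_result` from [score_block()].
#' @param ... Unused.
#' @method tidy synergy_result
#' @export
tidy.synergy_result <- function(x, ...) {
  purrr::map_dfr(x$surfaces, tidy_surface)
}

#' @method tidy synergy_surface
#' @export
tidy.synergy_surface <- function(x, ...) {
  tidy_surface(x)
}

tidy_surface <- function(s) {
  ns <- length(s$drugs)
  dose_cols <- purrr::map_dfc(seq_len(ns), function(k) {
    tibble::tibble(!!paste0("conc_", k) := s$doses[[k]][s$grid[, k]])
  })
  out <- dplyr::bind_cols(
    tibble::tibble(block_id = s$block_id,
                   drug_subset = paste(s$drugs, collapse = "+"),
                   subset_size = ns, model = s$model),
    dose_cols,
    tibble::tibble(measured = s$measured, expected = s$expected,
                   score = s$scores, replicate_sd = s$replicate_sd,
                   outlier = s$outlier_flag))
  if (!is.null(s$ci_sum)) out$loewe_ci <- s$ci_sum
  out
}

#' Summary synergy score of one surface
#'
#' The summary score is the arithmetic mean of the dose-wise synergy scores
#' over all measured, non-masked (non-outlier, if exclusion was requested)
#' interior wells. With replicates, the SD is the standard deviation of the
#' per-replicate summary means (each replicate scored against the shared
#' expected surface); it is absent without replication.
#'
#' @param surface A `synergy_surface`.
#' @return One-row tibble: `block_id`, `drug_subset`, `subset_size`,
#'   `model`, `summary_score`, `sd`, `n_wells`.
#' @export
summarize_surface <- function(surface) {
  stopifnot(inherits(surface, "synergy_surface"))
  use <- !is.na(surface$scores) & !surface$mask
  if (!any(use)) {
    abort(sprintf("all wells of %s/%s are masked or unmeasured; no summary",
                  paste(surface$drugs, collapse = "+"), surface$model),
          class = "combosyn_empty_summary")
  }
  rep_means <- apply(surface$replicate_scores[use, , drop = FALSE], 2,
                     function(col) if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE))
  rep_means <- rep_means[!is.na(rep_means)]
  tibble::tibble(
    block_id = surface$block_id,
    drug_subset = paste(surface$drugs, collapse = "+"),
    subset_size = length(surface$drugs),
    model = surface$model,
    summary_score = mean(surface$scores[use]),
    sd = if (length(rep_means) >= 2) stats::sd(rep_means) else NA_real_,
    n_wells = sum(use))
}

#' Summary scores for every sub-combination and model
#'
#' @param result A `synergy_result` from [score_block()].
#' @return Tibble with one row per drug subset x model, ordered by subset
#'   size, subset name, then the fixed model order HSA, Bliss, Loewe, ZIP.
#' @export
summarize_synergy <- function(result) {
  stopifnot(inherits(result, "synergy_result"))
  out <- purrr::map_dfr(result$surfaces, summarize_surface)
  out[order(out$subset_size, out$drug_subset,
            match(out$model, SYNERGY_MODELS)), ]
}

#' @method glance synergy_result
#' @export
glance.synergy_result <- function(x, ...) {
  s <- summarize_synergy(x)
  top <- s[s$subset_size == max(s$subset_size), ]
  tibble::tibble(block_id = x$block$block_id,
                 n_drugs = length(x$block$drugs),
                 design = x$design,
                 n_surfaces = length(x$surfaces),
                 models = paste(x$models, collapse = ","),
                 mean_top_order_score = mean(top$summary_score))
}
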