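#' Export per-well score and summary tables
#'
#' Writes two CSV files per scored block into `dir`:
#'
#' * `<block_id>__scores.csv` — one row per interior well per drug subset:
#'   `block_id`, `drug_subset`, `subset_size`, `conc_1..conc_K` (K = number
#'   of drugs in the largest subset; unused columns empty for smaller
#'   subsets), `measured`, `replicate_sd`, `outlier`, one `score_<model>`
#'   and `expected_<model>` column per scored model, and `loewe_ci` (the
#'   raw additivity sum at the measured effect) when Loewe was scored.
#' * `<block_id>__summary.csv` — one row per sub-combination x model:
#'   `summary_score` (mean of non-masked well scores), `sd` (replicate
#'   SD), `n_wells`.
#'
#' Rows are sorted by subset size, subset name, then dose columns; models
#' follow the fixed order HSA, Bliss, Loewe, ZIP. Re-running the writer on
#' identical inputs produces byte-identical files.
#'
#' @param results A `synergy_result` or list of them (one per block).
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_summary_tables <- function(results, dir) {
  if (inherits(results, "synergy_result")) results <- list(results)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  }
  paths <- character(0)
  for (res in results) {
    id <- res$block$block_id
    scores <- scores_wide(res)
    summary <- summarize_synergy(res)
    p1 <- file.path(dir, paste0(id, "__scores.csv"))
    p2 <- file.path(dir, paste0(id, "__summary.csv"))
    readr::write_csv(scores, p1)
    readr::write_csv(summary, p2)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}

# per-well long scores pivoted wide by model, deterministic column/row order
scores_wide <- function(res) {
  long <- tidy(res)
  conc_cols <- grep("^conc_", names(long), value = TRUE)
  key_cols <- c("block_id", "drug_subset", "subset_size", conc_cols,
                "measured", "replicate_sd", "outlier")
  wide <- tidyr::pivot_wider(
    long,
    id_cols = dplyr::all_of(c(key_cols,
                              if ("loewe_ci" %in% names(long)) character(0))),
    names_from = "model",
    values_from = dplyr::all_of(c("score", "expected")),
    names_glue = "{.value}_{model}")
  if ("loewe_ci" %in% names(long)) {
    ci <- long[long$model == "Loewe",
               c("drug_subset", conc_cols, "loewe_ci")]
    wide <- dplyr::left_join(wide, ci, by = c("drug_subset", conc_cols))
  }
  present <- intersect(SYNERGY_MODELS, unique(long$model))
  ordered_cols <- c(key_cols,
                    paste0("score_", present), paste0("expected_", present),
                    if ("loewe_ci" %in% names(wide)) "loewe_ci")
  wide <- wide[ordered_cols]
  wide[do.call(order, wide[c("subset_size", "drug_subset", conc_cols)]), ]
}
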