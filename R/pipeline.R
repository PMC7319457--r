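#' Run the full synergy-scoring pipeline
#'
#' Orchestrates read -> curve fit -> outlier detection -> synergy scoring ->
#' export for one or more input files: the engine behind the `combosyn`
#' command-line script (`system.file("scripts", "combosyn", package =
#' "combosyn")`).
#'
#' Per block it writes `<block_id>__scores.csv`, `<block_id>__summary.csv`
#' and `<block_id>__outliers.csv` into `out_dir`, plus one HTML report for
#' the chosen style. Each stage is logged with counts (blocks, wells,
#' outlier flags). Requesting Loewe or ZIP on a partial-design block is a
#' design-incompatible error (only Bliss and HSA scores can be calculated
#' there); other per-block failures are logged and skipped so remaining
#' blocks still complete. Given a fixed `seed`, reruns produce identical
#' CSV outputs.
#'
#' @param input Path(s) to input files.
#' @param out_dir Output directory.
#' @param dialect `"table"` or `"matrix"`.
#' @param readout `"inhibition"` or `"viability"`.
#' @param models Reference models to score.
#' @param curve_model Monotherapy curve family.
#' @param exclude_outliers Mask flagged wells out of the summaries.
#' @param outlier_threshold Outlier threshold in percentage points.
#' @param report_style `"short"`, `"static"` or `"dynamic-data"`.
#' @param seed Integer seed (outlier predictor initialisation).
#' @param verbose Log progress to stderr.
#' @return Invisibly, a list with `results` (per-block `synergy_result`),
#'   `outliers` (per-block reports) and `paths` (written files).
#' @export
run_synergy <- function(input, out_dir,
                        dialect = c("table", "matrix"),
                        readout = c("inhibition", "viability"),
                        models = SYNERGY_MODELS,
                        curve_model = c("4pl", "linear", "loess"),
                        exclude_outliers = FALSE, outlier_threshold = 20,
                        report_style = c("static", "short", "dynamic-data"),
                        seed = 1L, verbose = TRUE) {
  dialect <- match.arg(dialect)
  readout <- match.arg(readout)
  curve_model <- match.arg(curve_model)
  report_style <- match.arg(report_style)
  models <- match_models(models)
  log_msg <- function(...) if (verbose) message("[combosyn] ", sprintf(...))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  reader <- if (dialect == "table") read_combo_table else read_combo_matrix
  blocks <- list()
  for (path in input) {
    bl <- reader(path, readout = readout)
    log_msg("read %d block(s) from %s", length(bl), path)
    blocks <- c(blocks, bl)
  }
  results <- list(); outliers <- list(); paths <- character(0)
  for (block in blocks) {
    id <- block$block_id
    design <- block_design(block)
    if (design == "partial" && any(models %in% c("Loewe", "ZIP"))) {
      abort(paste0(
        "block ", id, " has a partial combination design; only the Bliss and ",
        "HSA synergy scores can be calculated. Re-run with --models HSA,Bliss ",
        "or supply multiple doses per drug."),
        class = "combosyn_design_error")
    }
    res <- tryCatch({
      orep <- detect_outliers(block, threshold_pp = outlier_threshold,
                              seed = seed)
      log_msg("block %s: %d wells, design = %s, %d outlier flag(s)",
              id, nrow(block$wells), design, orep$n_flagged)
      sres <- score_block(block, models = models, curve_model = curve_model,
                          outlier_report = orep,
                          exclude_outliers = exclude_outliers)
      list(scores = sres, outliers = orep)
    }, error = function(e) {
      if (inherits(e, "combosyn_design_error")) stop(e)
      log_msg("block %s failed and was skipped: %s", id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    results[[id]] <- res$scores
    outliers[[id]] <- res$outliers
    paths <- c(paths, write_summary_tables(res$scores, out_dir))
    op <- file.path(out_dir, paste0(id, "__outliers.csv"))
    readr::write_csv(tidy(res$outliers), op)
    paths <- c(paths, op)
  }
  if (length(results) > 0) {
    rp <- build_report(results, out_dir, style = report_style, models = models)
    paths <- c(paths, rp)
    log_msg("report written to %s", rp)
  }
  log_msg("done: %d of %d block(s) scored", length(results), length(blocks))
  invisible(list(results = results, outliers = outliers, paths = paths))
}

#' Parse a key=value run configuration file
#'
#' Plain-text configuration mirroring every command-line flag of the
#' `combosyn` script (one `key = value` pair per line, `#` comments).
#' Command-line flags win on conflict.
#'
#' @param path Configuration file.
#' @return Named list of character values.
#' @export
parse_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) {
    abort(sprintf("config line without `=`: \"%s\"", lines[bad][1]))
  }
  stats::setNames(
    lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
    vapply(kv, function(p) trimws(p[1]), character(1)))
}
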