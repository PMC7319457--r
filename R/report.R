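#' Assemble an HTML report for scored combination blocks
#'
#' Builds a single self-contained HTML file (images embedded as base64,
#' tables inlined) summarising one or more scored blocks. Three styles of
#' increasing completeness mirror the short/static/dynamic report types:
#'
#' * `"short"` — summary score tables and sub-combination barplots only.
#' * `"static"` — adds 2D synergy heatmaps and 3D landscapes per drug
#'   pair, and response tensor slice views for triplets.
#' * `"dynamic-data"` — the static report plus a machine-readable CSV
#'   bundle (per-well scores, summaries, and every plotted grid) so the
#'   synergy results can be processed in other analytical software.
#'
#' Models requested but not scored for a block are listed as unavailable
#' in the report rather than failing it. Rebuilding with identical inputs
#' reproduces the tables byte-identically (image bytes are device-
#' dependent and exempt).
#'
#' @param results A `synergy_result` or list of them.
#' @param dir Output directory.
#' @param style `"short"`, `"static"` or `"dynamic-data"`.
#' @param models Models to show (default: all models present in the
#'   results).
#' @param title Report title.
#' @return Path of the written HTML file, invisibly.
#' @export
build_report <- function(results, dir,
                         style = c("short", "static", "dynamic-data"),
                         models = NULL, title = "Drug combination synergy report") {
  style <- match.arg(style)
  if (inherits(results, "synergy_result")) results <- list(results)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_dir <- file.path(dir, "figures")
  csv_dir <- file.path(dir, "tables")
  dir.create(img_dir, showWarnings = FALSE)
  if (style == "dynamic-data") dir.create(csv_dir, showWarnings = FALSE)
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            sprintf("<title>%s</title>", title),
            "<style>body{font-family:sans-serif;max-width:70em;margin:auto}",
            "table{border-collapse:collapse;margin:1em 0}",
            "td,th{border:1px solid #ccc;padding:2px 8px;font-size:90%}",
            "img{max-width:100%}</style></head><body>",
            sprintf("<h1>%s</h1>", title),
            sprintf("<p>Report style: %s</p>", style))
  for (res in results) {
    id <- res$block$block_id
    shown <- if (is.null(models)) res$models else match_models(models)
    missing <- setdiff(shown, res$models)
    shown <- intersect(shown, res$models)
    html <- c(html, sprintf("<h2>Block %s (%s)</h2>", id,
                            paste(res$block$drugs, collapse = " + ")))
    if (length(missing) > 0) {
      html <- c(html, sprintf(
        "<p><em>Not available for this block: %s.</em></p>",
        paste(missing, collapse = ", ")))
    }
    summary_tbl <- summarize_synergy(res)
    summary_tbl <- summary_tbl[summary_tbl$model %in% shown, ]
    html <- c(html, "<h3>Summary synergy scores</h3>", html_table(summary_tbl))
    bar_png <- file.path(img_dir, paste0(id, "__bars.png"))
    save_plot(plot_subcombination_bars(summary_tbl), bar_png)
    html <- c(html, embed_img(bar_png))
    if (style != "short") {
      for (key in names(res$surfaces)) {
        surf <- res$surfaces[[key]]
        if (!surf$model %in% shown) next
        stem <- gsub("[^A-Za-z0-9]+", "_", paste(id, key))
        hm_png <- file.path(img_dir, paste0(stem, "__heatmap.png"))
        save_plot(plot_pair_landscape(surf), hm_png)
        html <- c(html, sprintf("<h3>%s &mdash; %s</h3>",
                                paste(surf$drugs, collapse = " + "),
                                surf$model),
                  embed_img(hm_png))
        if (length(surf$drugs) == 2) {
          p3d <- file.path(img_dir, paste0(stem, "__3d.png"))
          plot_landscape_3d(surf, p3d)
          html <- c(html, embed_img(p3d))
        }
        if (style == "dynamic-data") {
          readr::write_csv(landscape_grid(surf),
                           file.path(csv_dir, paste0(stem, "__grid.csv")))
        }
      }
      if (length(res$block$drugs) >= 3) {
        for (trip in utils::combn(res$block$drugs, 3, simplify = FALSE)) {
          stem <- gsub("[^A-Za-z0-9]+", "_",
                       paste(id, paste(trip, collapse = "_")))
          tv_png <- file.path(img_dir, paste0(stem, "__tensor.png"))
          save_plot(plot_tensor_slices(res$block, trip), tv_png)
          html <- c(html, sprintf("<h3>Response tensor: %s</h3>",
                                  paste(trip, collapse = " + ")),
                    embed_img(tv_png))
        }
      }
    }
    if (style == "dynamic-data") {
      write_summary_tables(res, csv_dir)
    }
  }
  html <- c(html, "</body></html>")
  out <- file.path(dir, paste0("synergy_report_", style, ".html"))
  writeLines(html, out)
  invisible(out)
}

save_plot <- function(p, file, width = 6.5, height = 4.5) {
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 96)
}

embed_img <- function(file) {
  raw <- readBin(file, "raw", file.size(file))
  sprintf("<img src='data:image/png;base64,%s'/>", jsonlite::base64_enc(raw))
}

html_table <- function(df) {
  fmt_cell <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 6, format = "g") else as.character(x)
  }
  cells <- vapply(df, fmt_cell, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  rows <- apply(cells, 1, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  })
  paste0("<table><tr>",
         paste0("<th>", names(df), "</th>", collapse = ""),
         "</tr>", paste(rows, collapse = ""), "</table>")
}
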