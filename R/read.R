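#' Read drug combination screening data (Table dialect)
#'
#' Reads the long "Table" input dialect: one row per well (per replicate),
#' with columns `block_id`, `drug_1` ... `drug_N`, `conc_1` ... `conc_N`,
#' `response` (percent scale), and optionally `conc_unit_1` ...
#' `conc_unit_N`. The number of drugs N is inferred from the column set.
#' CSV (comma), TSV/TXT (tab) and XLSX (first sheet unless `sheet` is
#' given) are accepted; UTF-8, decimal point only.
#'
#' Wells measured several times (identical coordinates) are always stacked
#' as replicates, never overwritten. Grid cells never measured are tracked
#' through the block's missing mask. Responses are converted to fractional
#' inhibition according to `readout`.
#'
#' @param path Input file.
#' @param readout `"inhibition"` or `"viability"` (percent scale of the
#'   response column).
#' @param sheet XLSX sheet (default first).
#' @return A list of `combo_block`, one per `block_id`.
#' @export
read_combo_table <- function(path, readout = c("inhibition", "viability"),
                             sheet = 1) {
  readout <- match.arg(readout)
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  df <- read_any_rectangular(path, sheet)
  parse_long_wells(df, readout, "percent", source_file = path)
}

read_any_rectangular <- function(path, sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    readxl::read_excel(path, sheet = sheet)
  } else if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Read drug combination screening data (Matrix dialect)
#'
#' Reads the wide "Matrix" dialect: one dose-response grid per block, two
#' drugs per block (higher-order data must use the table dialect). Each
#' block is laid out as
#'
#' ```
#' block_id,B1
#' drug_row,DrugA,unit,uM
#' drug_col,DrugB,unit,nM
#' conc,0,1,10
#' 0,0,5,12
#' 1,3,22,40
#' 10,9,45,78
#' ```
#'
#' with the row drug's doses down the first column and the column drug's
#' doses along the `conc` header. Blocks are separated by blank lines;
#' repeated grids with the same `block_id` are stacked as replicates.
#' `NA` cells mark unmeasured wells.
#'
#' @inheritParams read_combo_table
#' @return A list of `combo_block`, one per block id.
#' @export
read_combo_matrix <- function(path, readout = c("inhibition", "viability"),
                              sheet = 1) {
  readout <- match.arg(readout)
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  rows <- read_cell_rows(path, sheet)
  blocks_raw <- split_matrix_blocks(rows)
  if (length(blocks_raw) == 0) {
    abort("no matrix blocks found in file", class = "combosyn_parse_error")
  }
  parsed <- lapply(blocks_raw, parse_matrix_block)
  ids <- vapply(parsed, `[[`, character(1), "block_id")
  out <- lapply(split(parsed, ids), function(grids) {
    wells <- purrr::map_dfr(grids, function(g) {
      w <- g$wells
      w$drug_1 <- g$drugs[1]; w$drug_2 <- g$drugs[2]
      w$conc_unit_1 <- g$units[1]; w$conc_unit_2 <- g$units[2]
      w
    })
    wells$block_id <- grids[[1]]$block_id
    blks <- parse_long_wells(wells, readout, "percent", source_file = path)
    blks[[1]]
  })
  out[unique(ids)]
}

# file -> list of character row vectors (delimited text or xlsx)
read_cell_rows <- function(path, sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    df <- suppressMessages(
      readxl::read_excel(path, sheet = sheet, col_names = FALSE,
                         col_types = "text"))
    return(lapply(seq_len(nrow(df)), function(i) {
      r <- as.character(unlist(df[i, ], use.names = FALSE))
      r[is.na(r)] <- ""
      r
    }))
  }
  sep <- if (ext == "csv") "," else "\t"
  lines <- readLines(path, warn = FALSE)
  lapply(lines, function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1]]))
}

split_matrix_blocks <- function(rows) {
  nonblank <- vapply(rows, function(r) any(nzchar(r)), logical(1))
  blocks <- list()
  cur <- list()
  for (i in seq_along(rows)) {
    if (nonblank[i]) {
      cur[[length(cur) + 1]] <- rows[[i]]
    } else if (length(cur) > 0) {
      blocks[[length(blocks) + 1]] <- cur
      cur <- list()
    }
  }
  if (length(cur) > 0) blocks[[length(blocks) + 1]] <- cur
  blocks
}

parse_matrix_block <- function(rows) {
  key <- vapply(rows, function(r) tolower(r[1]), character(1))
  extra_drugs <- grepl("^drug_", key) & !key %in% c("drug_row", "drug_col")
  if (any(extra_drugs)) {
    abort("the matrix dialect supports 2 drugs per block; use the table dialect for higher-order combinations",
          class = "combosyn_unsupported_dialect")
  }
  need <- c("block_id", "drug_row", "drug_col", "conc")
  pos <- match(need, key)
  if (anyNA(pos)) {
    abort(paste0("matrix block is missing the `", need[which(is.na(pos))[1]],
                 "` line"), class = "combosyn_parse_error")
  }
  block_id <- rows[[pos[1]]][2]
  drugs <- c(rows[[pos[2]]][2], rows[[pos[3]]][2])
  get_unit <- function(r) if (length(r) >= 4 && tolower(r[3]) == "unit") r[4] else NA_character_
  units <- c(get_unit(rows[[pos[2]]]), get_unit(rows[[pos[3]]]))
  header <- rows[[pos[4]]]
  col_doses <- parse_num(header[-1], "column dose header")
  data_rows <- rows[seq_along(rows) > pos[4]]
  if (length(data_rows) == 0) {
    abort("matrix block has no dose rows", class = "combosyn_parse_error")
  }
  row_doses <- numeric(0)
  vals <- list()
  for (r in data_rows) {
    if (length(r) != length(col_doses) + 1) {
      abort(sprintf(
        "ragged matrix grid: dose row `%s` has %d value(s), header has %d dose(s)",
        r[1], length(r) - 1, length(col_doses)), class = "combosyn_parse_error")
    }
    row_doses <- c(row_doses, parse_num(r[1], "row dose"))
    vals[[length(vals) + 1]] <- parse_num_na(r[-1], "response")
  }
  grid <- do.call(rbind, vals)
  wells <- tibble::tibble(
    conc_1 = rep(row_doses, times = length(col_doses)),
    conc_2 = rep(col_doses, each = length(row_doses)),
    response = as.numeric(grid))
  wells <- wells[!is.na(wells$response), ]
  list(block_id = block_id, drugs = drugs, units = units, wells = wells)
}

parse_num <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    abort(sprintf("non-numeric %s: \"%s\"", what, x[which(is.na(out))[1]]),
          class = "combosyn_parse_error")
  }
  out
}

parse_num_na <- function(x, what) {
  ok_na <- is.na(x) | toupper(trimws(x)) == "NA" | trimws(x) == ""
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out) & !ok_na)) {
    abort(sprintf("non-numeric %s: \"%s\"", what,
                  x[which(is.na(out) & !ok_na)[1]]),
          class = "combosyn_parse_error")
  }
  out
}
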