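#' Dose-response combination blocks
#'
#' A `combo_block` holds one screened drug combination: an N-way
#' dose-response tensor indexed by per-drug dose ladders (each ladder
#' includes dose 0, the untreated/monotherapy anchor), with an optional
#' replicate axis. Responses are stored as fractional inhibition (see
#' [normalize_readout()]); wells on the grid that were never measured are
#' tracked through a missing mask.
#'
#' The design is `"full"` when every drug has at least two nonzero doses and
#' the grid is completely measured, `"partial"` otherwise (some drug at one
#' fixed dose, or holes in the grid). Partial designs support only the HSA
#' and Bliss reference models, because Loewe and ZIP need fitted
#' monotherapy curves and hence multiple doses per drug.
#'
#' @param data A data frame in the long ("Table") layout: columns
#'   `block_id` (optional if `block_id` given), `drug_1` ... `drug_N`,
#'   `conc_1` ... `conc_N`, `response`, and optionally
#'   `conc_unit_1` ... `conc_unit_N`. One row per well per replicate;
#'   repeated coordinates are stacked as replicates.
#' @param readout `"inhibition"` or `"viability"`; the percent responses are
#'   converted to fractional inhibition accordingly.
#' @param block_id Optional block identifier when `data` lacks a
#'   `block_id` column.
#' @param response_scale `"percent"` (default, file convention) or
#'   `"fraction"` if the response column is already fractional inhibition.
#' @return For [as_combo_block()], a single `combo_block` (the data must
#'   contain exactly one block id).
#' @examples
#' wells <- expand.grid(conc_1 = c(0, 1, 10), conc_2 = c(0, 1, 10))
#' wells$drug_1 <- "A"; wells$drug_2 <- "B"
#' wells$response <- 100 * (wells$conc_1 / 10 + wells$conc_2 / 20)
#' blk <- as_combo_block(wells, block_id = "demo")
#' blk
#' @export
as_combo_block <- function(data, readout = c("inhibition", "viability"),
                           block_id = NULL, response_scale = c("percent", "fraction")) {
  readout <- match.arg(readout)
  response_scale <- match.arg(response_scale)
  if (!is.null(block_id) && !"block_id" %in% names(data)) {
    data$block_id <- block_id
  }
  blocks <- parse_long_wells(data, readout, response_scale)
  if (length(blocks) != 1) {
    abort(sprintf("expected exactly one block id, found %d; use the reader functions for multi-block files",
                  length(blocks)))
  }
  blocks[[1]]
}

# shared long-format parser: data frame -> list of combo_block
parse_long_wells <- function(data, readout, response_scale = "percent",
                             source_file = NULL) {
  data <- tibble::as_tibble(data)
  n <- 1
  while (all(c(paste0("drug_", n + 1), paste0("conc_", n + 1)) %in% names(data))) {
    n <- n + 1
  }
  required <- c("block_id", paste0("drug_", seq_len(n)),
                paste0("conc_", seq_len(n)), "response")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
          class = "combosyn_schema_error")
  }
  conc_cols <- paste0("conc_", seq_len(n))
  for (col in c(conc_cols, "response")) {
    vals <- data[[col]]
    if (!is.numeric(vals)) {
      coerced <- suppressWarnings(as.numeric(vals))
      bad <- which(is.na(coerced) & !is.na(vals) & trimws(as.character(vals)) != "")
      if (length(bad) > 0) {
        abort(sprintf("non-numeric value in column `%s` at data row %d: \"%s\"",
                      col, bad[1], as.character(vals[bad[1]])),
              class = "combosyn_parse_error")
      }
      data[[col]] <- coerced
    }
  }
  unit_cols <- paste0("conc_unit_", seq_len(n))
  split_idx <- split(seq_len(nrow(data)), data$block_id)
  purrr::imap(split_idx, function(rows, id) {
    d <- data[rows, ]
    drugs <- vapply(seq_len(n), function(k) {
      nm <- unique(d[[paste0("drug_", k)]])
      nm <- nm[!is.na(nm)]
      if (length(nm) != 1) {
        abort(sprintf("block %s: column drug_%d must carry a single drug name", id, k),
              class = "combosyn_schema_error")
      }
      as.character(nm)
    }, character(1))
    units <- vapply(seq_len(n), function(k) {
      uc <- unit_cols[k]
      if (uc %in% names(d)) as.character(d[[uc]][1]) else NA_character_
    }, character(1))
    eff <- if (response_scale == "percent") {
      normalize_readout(d$response, readout)
    } else d$response
    wells <- d[conc_cols]
    wells$effect <- eff
    wells <- dplyr::mutate(
      dplyr::group_by(wells, dplyr::across(dplyr::all_of(conc_cols))),
      replicate = dplyr::row_number())
    wells <- dplyr::ungroup(wells)
    new_combo_block(
      block_id = as.character(id), drugs = drugs,
      wells = wells, units = units, readout = readout,
      metadata = if (is.null(source_file)) list() else list(source = source_file))
  })
}

new_combo_block <- function(block_id, drugs, wells, units = NULL,
                            readout = "inhibition", metadata = list()) {
  n <- length(drugs)
  conc_cols <- paste0("conc_", seq_len(n))
  doses <- lapply(conc_cols, function(cc) sort(unique(wells[[cc]])))
  names(doses) <- drugs
  for (k in seq_len(n)) {
    if (!0 %in% doses[[k]]) {
      abort(sprintf(
        "block %s: drug %s has no dose-0 (untreated control) wells; every reference model needs monotherapy anchors",
        block_id, drugs[k]), class = "combosyn_schema_error")
    }
    if (any(doses[[k]] < 0)) {
      abort(sprintf("block %s: negative dose for drug %s", block_id, drugs[k]),
            class = "combosyn_parse_error")
    }
  }
  structure(list(
    block_id = block_id, drugs = drugs, doses = doses,
    units = units %||% rep(NA_character_, n),
    wells = tibble::as_tibble(wells[c(conc_cols, "effect", "replicate")]),
    readout = readout, metadata = metadata
  ), class = "combo_block")
}

#' @export
print.combo_block <- function(x, ...) {
  dims <- lengths(x$doses)
  cat("<combo_block> ", x$block_id, ": ",
      paste(x$drugs, collapse = " + "), "\n", sep = "")
  cat("  grid ", paste(dims, collapse = " x "),
      " (doses incl. 0), ", nrow(x$wells), " measurements, design = ",
      block_design(x), "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname as_combo_block
#' @param x A `combo_block`.
#' @param ... Unused.
tidy.combo_block <- function(x, ...) {
  n <- length(x$drugs)
  out <- x$wells
  for (k in seq_len(n)) out[[paste0("drug_", k)]] <- x$drugs[k]
  dplyr::bind_cols(tibble::tibble(block_id = x$block_id),
                   out[c(paste0("drug_", seq_len(n)),
                         paste0("conc_", seq_len(n)), "effect", "replicate")])
}

#' Tensor views of a combination block
#'
#' `response_array()` returns the replicate-mean N-way fractional
#' inhibition array over the dose-ladder grid (unmeasured wells `NA`);
#' `replicate_array()` the same grid with a trailing replicate axis
#' (NA-padded); `missing_mask()` the boolean array marking unmeasured
#' wells.
#'
#' @param block A `combo_block`.
#' @return An array (see above).
#' @export
response_array <- function(block) {
  n <- length(block$drugs)
  dims <- unname(lengths(block$doses))
  arr <- array(NA_real_, dim = dims,
               dimnames = unname(lapply(block$doses,
                                        function(d) format(d, trim = TRUE))))
  idx <- well_indices(block)
  means <- tapply(block$wells$effect, idx, mean)
  arr[as.integer(names(means))] <- as.numeric(means)
  arr
}

#' @rdname response_array
#' @export
replicate_array <- function(block) {
  dims <- unname(lengths(block$doses))
  nrep <- max(block$wells$replicate)
  arr <- array(NA_real_, dim = c(dims, nrep))
  flat <- well_indices(block)
  arr[flat + (block$wells$replicate - 1) * prod(dims)] <- block$wells$effect
  arr
}

# linear index of each measurement row into the dose grid
well_indices <- function(block) {
  n <- length(block$drugs)
  dims <- unname(lengths(block$doses))
  sub <- vapply(seq_len(n), function(k) {
    match(block$wells[[paste0("conc_", k)]], block$doses[[k]])
  }, integer(nrow(block$wells)))
  sub <- matrix(sub, ncol = n)
  1L + as.integer((sub - 1L) %*% cumprod(c(1L, dims[-n])))
}

#' @rdname response_array
#' @export
missing_mask <- function(block) {
  is.na(response_array(block))
}

#' Combination design of a block
#'
#' `"partial"` when any drug is measured at a single nonzero dose or the
#' dose grid has unmeasured wells; `"full"` otherwise. Partial designs
#' support only the HSA and Bliss synergy models.
#'
#' @param block A `combo_block`.
#' @return `"full"` or `"partial"`.
#' @export
block_design <- function(block) {
  single <- any(vapply(block$doses, function(d) sum(d > 0) < 2, logical(1)))
  if (single || any(missing_mask(block))) "partial" else "full"
}

# block restricted to a drug subset: wells where all other drugs are at dose 0
slice_block <- function(block, drugs) {
  stopifnot(all(drugs %in% block$drugs))
  keep_k <- match(drugs, block$drugs)
  other_k <- setdiff(seq_along(block$drugs), keep_k)
  w <- block$wells
  for (k in other_k) w <- w[w[[paste0("conc_", k)]] == 0, ]
  w2 <- w[c(paste0("conc_", keep_k), "effect", "replicate")]
  names(w2) <- c(paste0("conc_", seq_along(keep_k)), "effect", "replicate")
  new_combo_block(block$block_id, block$drugs[keep_k], w2,
                  units = block$units[keep_k], readout = block$readout,
                  metadata = block$metadata)
}

# pooled monotherapy (dose, effect) points for one drug, replicates stacked
monotherapy_points <- function(block, drug) {
  k <- match(drug, block$drugs)
  if (is.na(k)) abort(sprintf("drug %s not in block %s", drug, block$block_id))
  w <- block$wells
  for (j in setdiff(seq_along(block$drugs), k)) {
    w <- w[w[[paste0("conc_", j)]] == 0, ]
  }
  tibble::tibble(dose = w[[paste0("conc_", k)]], effect = w$effect,
                 replicate = w$replicate)
}

#' Fit monotherapy curves for every drug in a block
#'
#' Extracts each drug's monotherapy slice (wells where all other drugs are
#' at dose 0), pools replicates, and fits a dose-response curve per drug.
#' These fitted curves feed the Loewe and ZIP reference models.
#'
#' @param block A `combo_block`.
#' @param model Curve family passed to [fit_dose_response()].
#' @param span LOESS span, if `model = "loess"`.
#' @return Named list of `dose_response_curve` objects (one per drug).
#' @export
fit_monotherapies <- function(block, model = c("4pl", "linear", "loess"),
                              span = 0.75) {
  model <- match.arg(model)
  curves <- lapply(block$drugs, function(drug) {
    pts <- monotherapy_points(block, drug)
    fit_dose_response(pts$dose, pts$effect, model = model, span = span)
  })
  names(curves) <- block$drugs
  curves
}
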