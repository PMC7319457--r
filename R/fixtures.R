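#' Specify a synthetic dose-response fixture
#'
#' Builds the specification of a synthetic combination block with known
#' ground truth: per-drug 4PL monotherapy curves, a declared no-interaction
#' null model for the interior wells, an optional planted synergy offset,
#' replicate Gaussian noise, and optional single-well outlier injections.
#' When `noise_sd = 0`, `synergy_offset = 0` and no injections are given,
#' the generated tensor satisfies its declared null exactly, so the
#' matching synergy score is zero by construction.
#'
#' Defaults emulate a routine two-drug screen: six-point ladders (dose 0
#' plus five half-log-spaced doses spanning the midpoint), unit midpoint
#' doses, Hill slope 1, full 0-to-1 effect window. Fixture curves must have
#' `e_min = 0` (untreated wells show no inhibition), which also makes the
#' Bliss and ZIP nulls coincide.
#'
#' @param n_drugs Number of drugs (>= 2).
#' @param curves List of per-drug parameter lists `(e_min, e_max, m,
#'   lambda)`; recycled defaults if omitted.
#' @param dose_ladders List of per-drug dose vectors, each including 0.
#' @param null_model Interior-well generator: `"Bliss"`, `"HSA"`,
#'   `"Loewe-sham"` (all drugs must share one curve) or `"ZIP"`.
#' @param synergy_offset Additive fractional-effect offset planted on
#'   interior wells (all doses > 0).
#' @param offset_region Optional predicate `function(doses) -> logical`
#'   restricting the offset to a dose region.
#' @param noise_sd Replicate noise SD on the fractional effect scale
#'   (Gaussian, truncated to `[-0.2, 1.2]`).
#' @param n_replicates Number of replicates per well.
#' @param outlier_injections List of `list(well = <grid index vector>,
#'   shift = <effect shift>)`, applied last to all replicates of the well.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_drugs = 2, curves = NULL, dose_ladders = NULL,
                         null_model = c("Bliss", "HSA", "Loewe-sham", "ZIP"),
                         synergy_offset = 0, offset_region = NULL,
                         noise_sd = 0, n_replicates = 1,
                         outlier_injections = list(), seed = 1L) {
  null_model <- match.arg(null_model)
  if (n_drugs < 2) abort("a combination fixture needs at least 2 drugs")
  if (is.null(curves)) {
    curves <- replicate(n_drugs,
                        list(e_min = 0, e_max = 1, m = 1, lambda = 1),
                        simplify = FALSE)
  }
  if (length(curves) != n_drugs) abort("one curve parameter set per drug required")
  for (p in curves) {
    if (!isTRUE(all.equal(p$e_min, 0))) {
      abort("fixture curves must have e_min = 0 (no inhibition untreated)")
    }
  }
  if (null_model == "Loewe-sham") {
    first <- curves[[1]]
    same <- all(vapply(curves, function(p) identical(unlist(p), unlist(first)),
                       logical(1)))
    if (!same) {
      abort("Loewe-sham fixtures require all drugs to share one curve",
            class = "combosyn_fixture_error")
    }
  }
  if (is.null(dose_ladders)) {
    dose_ladders <- lapply(curves, function(p) {
      c(0, p$m * 10^seq(-1, 1, length.out = 5))
    })
  }
  if (length(dose_ladders) != n_drugs) abort("one dose ladder per drug required")
  for (d in dose_ladders) {
    if (!0 %in% d) abort("every fixture dose ladder must include dose 0")
  }
  structure(list(
    n_drugs = n_drugs, drugs = LETTERS[seq_len(n_drugs)], curves = curves,
    dose_ladders = lapply(dose_ladders, sort), null_model = null_model,
    synergy_offset = synergy_offset, offset_region = offset_region,
    noise_sd = noise_sd, n_replicates = n_replicates,
    outlier_injections = outlier_injections, seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' Generate a combination block with known ground truth
#'
#' Realises a [fixture_spec()]: monotherapy slices are drawn from the stated
#' curves, interior wells from the declared null model plus the planted
#' offset, replicates add seeded truncated-Gaussian noise, and outlier
#' injections are applied last.
#'
#' @param spec A `fixture_spec`.
#' @param block_id Identifier for the generated block.
#' @return List with `block` (a `combo_block`) and `truth` (the noiseless
#'   tensor, curve parameters, offset and injected wells).
#' @examples
#' fx <- simulate_combo_block(fixture_spec(synergy_offset = 0.15, seed = 3))
#' summarize_synergy(score_block(fx$block, "Bliss"))
#' @export
simulate_combo_block <- function(spec, block_id = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_drugs
  ladders <- spec$dose_ladders
  dims <- lengths(ladders)
  grid <- as.matrix(expand.grid(lapply(dims, seq_len)))
  dose_mat <- vapply(seq_len(n), function(k) ladders[[k]][grid[, k]],
                     numeric(nrow(grid)))
  dose_mat <- matrix(dose_mat, ncol = n)
  mono_eff <- vapply(seq_len(n), function(k) {
    p <- spec$curves[[k]]
    fourpl_fun(dose_mat[, k], p$e_min, p$e_max, p$m, p$lambda)
  }, numeric(nrow(grid)))
  mono_eff <- matrix(mono_eff, ncol = n)
  truth <- switch(spec$null_model,
    "Bliss" = 1 - apply(1 - pmin(pmax(mono_eff, 0), 1), 1, prod),
    "HSA" = apply(mono_eff, 1, max),
    "Loewe-sham" = {
      p <- spec$curves[[1]]
      fourpl_fun(rowSums(dose_mat), p$e_min, p$e_max, p$m, p$lambda)
    },
    "ZIP" = {
      pmat <- vapply(seq_len(n), function(k) {
        p <- spec$curves[[k]]
        t <- ifelse(dose_mat[, k] <= 0, 0, (dose_mat[, k] / p$m)^p$lambda)
        t / (1 + t)
      }, numeric(nrow(grid)))
      1 - apply(1 - matrix(pmat, ncol = n), 1, prod)
    })
  interior <- rowSums(dose_mat > 0) == n
  offset_on <- interior
  if (!is.null(spec$offset_region)) {
    offset_on <- interior & apply(dose_mat, 1, spec$offset_region)
  }
  truth <- truth + spec$synergy_offset * offset_on
  nrep <- spec$n_replicates
  eff <- with_seed(spec$seed, {
    noise <- if (spec$noise_sd > 0) {
      rnorm(length(truth) * nrep, 0, spec$noise_sd)
    } else rep(0, length(truth) * nrep)
    matrix(pmin(pmax(rep(truth, nrep) + noise, -0.2), 1.2),
           ncol = nrep)
  })
  for (inj in spec$outlier_injections) {
    w <- which(apply(grid, 1, function(g) all(g == inj$well)))
    if (length(w) != 1) abort("outlier injection well index outside the grid")
    eff[w, ] <- eff[w, ] + inj$shift
  }
  wells <- purrr::map_dfr(seq_len(nrep), function(r) {
    w <- tibble::as_tibble(as.data.frame(dose_mat))
    names(w) <- paste0("conc_", seq_len(n))
    w$effect <- eff[, r]
    w$replicate <- r
    w
  })
  block <- new_combo_block(block_id, spec$drugs, wells,
                           units = rep("uM", n), readout = "inhibition",
                           metadata = list(fixture = TRUE, seed = spec$seed))
  list(block = block,
       truth = list(tensor = array(truth, dim = dims), curves = spec$curves,
                    null_model = spec$null_model,
                    synergy_offset = spec$synergy_offset,
                    injections = spec$outlier_injections))
}

#' Write a block to disk in an input dialect
#'
#' Serialises a `combo_block` to the table (long) or matrix (2-drug wide)
#' input dialect so that the matching reader parses it back to the same
#' tensor. Responses are written on the percent scale of the requested
#' readout. Serves as the shipped example-data generator
#' (`combosyn fixtures` on the command line).
#'
#' @param block A `combo_block`.
#' @param path Output file (`.csv` or `.tsv`/`.txt`).
#' @param dialect `"table"` or `"matrix"` (matrix supports 2 drugs only).
#' @param readout Percent scale to write: `"inhibition"` or `"viability"`.
#' @return `path`, invisibly.
#' @export
write_combo_file <- function(block, path, dialect = c("table", "matrix"),
                             readout = c("inhibition", "viability")) {
  dialect <- match.arg(dialect)
  readout <- match.arg(readout)
  stopifnot(inherits(block, "combo_block"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  to_percent <- function(eff) if (readout == "inhibition") 100 * eff else 100 - 100 * eff
  if (dialect == "table") {
    n <- length(block$drugs)
    out <- tidy(block)
    out$response <- to_percent(out$effect)
    out$effect <- NULL
    out$replicate <- NULL
    for (k in seq_len(n)) out[[paste0("conc_unit_", k)]] <- block$units[k]
    if (sep == ",") readr::write_csv(out, path) else readr::write_tsv(out, path)
    return(invisible(path))
  }
  if (length(block$drugs) != 2) {
    abort("the matrix dialect supports exactly 2 drugs per block; use the table dialect for higher-order data",
          class = "combosyn_fixture_error")
  }
  R <- replicate_array(block)
  nrep <- dim(R)[3]
  lines <- character(0)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  for (r in seq_len(nrep)) {
    lines <- c(lines,
      paste(c("block_id", block$block_id), collapse = sep),
      paste(c("drug_row", block$drugs[1], "unit", block$units[1]), collapse = sep),
      paste(c("drug_col", block$drugs[2], "unit", block$units[2]), collapse = sep),
      paste(c("conc", fmt(block$doses[[2]])), collapse = sep))
    for (i in seq_along(block$doses[[1]])) {
      vals <- to_percent(R[i, , r])
      lines <- c(lines, paste(c(fmt(block$doses[[1]][i]),
                                fmt(vals)), collapse = sep))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
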