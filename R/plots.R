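#' Gridded score export of a synergy surface
#'
#' Machine-readable twin of the landscape figures: one row per plotted
#' cell, with the component doses, the score, and the expected and
#' measured effects. Figures and this grid always agree to full precision.
#'
#' @param surface A `synergy_surface`.
#' @return Tibble mirroring the plotted grid.
#' @export
landscape_grid <- function(surface) {
  stopifnot(inherits(surface, "synergy_surface"))
  tidy_surface(surface)
}

#' 2D synergy heatmap for a drug pair
#'
#' Heatmap of dose-wise synergy scores with the first two subset drugs on
#' the axes. For subsets of more than two drugs, one facet is drawn per
#' dose combination of the remaining drugs. The colour scale is diverging,
#' centred at 0 (antagonism blue, synergy red) with symmetric limits.
#'
#' @param surface A `synergy_surface` with >= 2 drugs.
#' @return A ggplot object.
#' @export
plot_pair_landscape <- function(surface) {
  df <- landscape_grid(surface)
  ns <- length(surface$drugs)
  lim <- max(abs(df$score), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1e-6
  df$x <- factor(df$conc_1, levels = surface$doses[[1]])
  df$y <- factor(df$conc_2, levels = surface$doses[[2]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$score)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-lim, lim),
                                  name = paste0(surface$model, "\nscore")) +
    ggplot2::labs(
      x = paste0(surface$drugs[1], " dose"),
      y = paste0(surface$drugs[2], " dose"),
      title = paste0(surface$block_id, ": ",
                     paste(surface$drugs, collapse = " + "),
                     " (", surface$model, ")")) +
    ggplot2::theme_minimal()
  if (ns > 2) {
    facet_cols <- paste0("conc_", 3:ns)
    lab <- paste0(surface$drugs[3:ns], "=")
    for (j in seq_along(facet_cols)) {
      df[[facet_cols[j]]] <- paste0(lab[j], df[[facet_cols[j]]])
    }
    p <- p %+% df + ggplot2::facet_wrap(facet_cols)
  }
  p
}

#' @method autoplot synergy_surface
#' @export
autoplot.synergy_surface <- function(object, ...) plot_pair_landscape(object)

# needed for `%+%` rebinding in faceting
`%+%` <- ggplot2::`%+%`

#' Static 3D synergy landscape for a two-drug surface
#'
#' Perspective rendering of the dose-wise synergy surface (doses on the
#' base axes, score as height), written to a PNG file.
#'
#' @param surface A 2-drug `synergy_surface`.
#' @param file Output PNG path.
#' @param theta,phi Viewing angles passed to [graphics::persp()].
#' @return `file`, invisibly.
#' @export
plot_landscape_3d <- function(surface, file, theta = 35, phi = 25) {
  stopifnot(inherits(surface, "synergy_surface"))
  if (length(surface$drugs) != 2) {
    abort("3D landscapes are drawn per two-drug surface")
  }
  z <- array(surface$scores, dim = surface$dims)
  z[is.na(z)] <- 0
  grDevices::png(file, width = 640, height = 560, res = 96)
  on.exit(grDevices::dev.off())
  nrz <- nrow(z); ncz <- ncol(z)
  zf <- (z[-1, -1] + z[-1, -ncz] + z[-nrz, -1] + z[-nrz, -ncz]) / 4
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  lim <- max(abs(z), 1e-6)
  cols <- pal[cut(zf, breaks = seq(-lim, lim, length.out = 65),
                  include.lowest = TRUE)]
  graphics::persp(seq_len(nrz), seq_len(ncz), z, theta = theta, phi = phi,
                  col = cols, ticktype = "detailed",
                  xlab = paste0(surface$drugs[1], " (dose rank)"),
                  ylab = paste0(surface$drugs[2], " (dose rank)"),
                  zlab = paste0(surface$model, " score"),
                  main = paste(surface$block_id,
                               paste(surface$drugs, collapse = "+"),
                               surface$model))
  invisible(file)
}

#' Summary barplot over all sub-combinations
#'
#' One bar per sub-combination (grouped by subset size, faceted by model),
#' with replicate-SD error bars when available. Bar heights equal the
#' `summary_score` column exactly.
#'
#' @param summary_tbl Output of [summarize_synergy()].
#' @return A ggplot object.
#' @export
plot_subcombination_bars <- function(summary_tbl) {
  df <- summary_tbl
  df$drug_subset <- factor(df$drug_subset, levels = unique(df$drug_subset))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$drug_subset,
                                        y = .data$summary_score,
                                        fill = factor(.data$subset_size))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "subset size") +
    ggplot2::labs(x = NULL, y = "summary synergy score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (any(!is.na(df$sd))) {
    eb <- df[!is.na(df$sd), ]
    p <- p + ggplot2::geom_errorbar(
      data = eb,
      ggplot2::aes(ymin = .data$summary_score - .data$sd,
                   ymax = .data$summary_score + .data$sd),
      width = 0.25)
  }
  if (length(unique(df$model)) > 1) {
    p <- p + ggplot2::facet_wrap(~model)
  }
  p
}

#' Dose-response tensor slices for a drug triplet
#'
#' Small-multiple heatmaps of the measured responses of drugs (A, B), one
#' panel per dose of drug C, on a shared colour scale spanning the global
#' response range.
#'
#' @param block A `combo_block`.
#' @param drugs Character vector of exactly 3 drug names in the block
#'   (default: the first three).
#' @return A ggplot object.
#' @export
plot_tensor_slices <- function(block, drugs = head(block$drugs, 3)) {
  stopifnot(inherits(block, "combo_block"))
  if (length(drugs) != 3 || !all(drugs %in% block$drugs)) {
    abort("tensor slice views require exactly 3 drugs from the block")
  }
  sub <- slice_block(block, drugs)
  A <- response_array(sub)
  grid <- as.matrix(expand.grid(lapply(dim(A), seq_len)))
  df <- tibble::tibble(
    x = factor(sub$doses[[1]][grid[, 1]], levels = sub$doses[[1]]),
    y = factor(sub$doses[[2]][grid[, 2]], levels = sub$doses[[2]]),
    slice = paste0(drugs[3], " = ", sub$doses[[3]][grid[, 3]]),
    response = A[grid])
  df$slice <- factor(df$slice, levels = unique(df$slice))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$response)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_viridis_c(limits = range(df$response, na.rm = TRUE),
                                  name = "inhibition") +
    ggplot2::facet_wrap(~slice) +
    ggplot2::labs(x = paste0(drugs[1], " dose"), y = paste0(drugs[2], " dose"),
                  title = paste0(block$block_id, ": response tensor slices")) +
    ggplot2::theme_minimal()
}
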