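# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# weighted (masked) NMF by multiplicative updates; V >= 0, M binary mask
nmf_complete <- function(V, M, rank, seed, maxit = 2000, tol = 1e-12) {
  nr <- nrow(V); nc <- ncol(V)
  scale0 <- sqrt(max(mean(V[M]), 1e-6) / rank)
  init <- with_seed(seed, list(
    W = matrix(runif(nr * rank, 0.5, 1.5) * scale0, nr, rank),
    H = matrix(runif(rank * nc, 0.5, 1.5) * scale0, rank, nc)))
  W <- init$W; H <- init$H
  MV <- M * V
  eps <- 1e-12
  obj_prev <- Inf
  for (it in seq_len(maxit)) {
    WH <- W %*% H
    W <- W * (MV %*% t(H)) / ((M * WH) %*% t(H) + eps)
    WH <- W %*% H
    H <- H * (t(W) %*% MV) / (t(W) %*% (M * WH) + eps)
    if (it %% 25 == 0) {
      obj <- sum((M * (V - W %*% H))^2)
      if (is.finite(obj_prev) && abs(obj_prev - obj) <= tol * max(obj_prev, eps)) break
      obj_prev <- obj
    }
  }
  W %*% H
}

# matricize an N-way array: rows = first axis, columns = remaining flattened
matricize <- function(arr) {
  d <- dim(arr)
  if (length(d) < 2) stop("array must have >= 2 axes")
  matrix(arr, nrow = d[1], ncol = prod(d[-1]))
}

#' Predict the full dose-response tensor from its overall pattern
#'
#' Pattern-based prediction of every measured well, used to flag outlier
#' measurements. The replicate-mean inhibition tensor is matricized (rows =
#' first drug's dose ladder, columns = the remaining axes flattened) and
#' completed by non-negative matrix factorization with masked
#' (leave-one-out) cells: each well's prediction is computed with that well
#' hidden from the factorization, so a single aberrant measurement cannot
#' drag its own prediction. The factorization rank is chosen from
#' `rank_candidates` by masked-cell cross-validation (a seeded 20% holdout
#' of the observed cells). Negative inhibition values are clamped to 0
#' before factorization (non-negativity); predictions are reported on the
#' fractional inhibition scale.
#'
#' Tensors with fewer than 3 doses on some ladder carry too little pattern
#' for completion; these fall back to a smooth reference-surface predictor
#' (the Bliss expectation of fitted monotherapy curves). The predictor sits
#' behind this one interface so an alternative matrix-completion model can
#' be swapped in.
#'
#' @param block A `combo_block`.
#' @param rank_candidates Integer ranks tried in cross-validation.
#' @param seed Integer seed controlling initialisation and the holdout.
#' @param exclude Optional boolean array (tensor shape) of wells to hide
#'   from the factorization entirely (they still receive predictions);
#'   used by [detect_outliers()] to refine flags so that one aberrant well
#'   cannot distort its neighbours' predictions.
#' @return List with `predicted` (array shaped like the tensor, `NA` where
#'   no prediction is available), `rank`, and `method`.
#' @export
predict_full_tensor <- function(block, rank_candidates = 1:3, seed = 1L,
                                exclude = NULL) {
  stopifnot(inherits(block, "combo_block"))
  A <- response_array(block)
  if (any(lengths(block$doses) < 3)) {
    return(smooth_reference_prediction(block, A))
  }
  V <- matricize(pmax(A, 0))
  V[is.na(V)] <- 0
  M <- matricize(!is.na(A)) * 1
  obs <- which(M == 1)
  if (!is.null(exclude)) M[matricize(exclude) > 0] <- 0
  # rows/columns with no observed cell at all cannot be predicted
  ok_row <- rowSums(M) > 0; ok_col <- colSums(M) > 0
  rank_candidates <- rank_candidates[rank_candidates < min(dim(V))]
  if (length(rank_candidates) == 0) rank_candidates <- 1L
  rank <- rank_candidates[1]
  if (length(rank_candidates) > 1 && length(obs) >= 10) {
    hold <- with_seed(seed, sample(obs, max(1, floor(0.2 * length(obs)))))
    M_cv <- M; M_cv[hold] <- 0
    cv_err <- vapply(rank_candidates, function(r) {
      P <- nmf_complete(V, M_cv, r, seed = seed + r)
      sqrt(mean((P[hold] - V[hold])^2))
    }, numeric(1))
    rank <- rank_candidates[which.min(cv_err)]
  }
  P <- matrix(NA_real_, nrow(V), ncol(V))
  for (cell in obs) {
    rc <- arrayInd(cell, dim(V))
    if (!ok_row[rc[1]] || !ok_col[rc[2]]) next
    M_loo <- M; M_loo[cell] <- 0
    if (sum(M_loo[rc[1], ]) == 0 || sum(M_loo[, rc[2]]) == 0) next
    fit <- nmf_complete(V, M_loo, rank, seed = seed)
    P[cell] <- fit[cell]
  }
  # predictions live on the fractional inhibition scale: extrapolation
  # outside [0, 1] is never evidence against a well
  P <- pmin(pmax(P, 0), 1)
  predicted <- array(P, dim = dim(A), dimnames = dimnames(A))
  predicted[is.na(A)] <- NA_real_
  list(predicted = predicted, rank = rank, method = "loo_nmf")
}

smooth_reference_prediction <- function(block, A) {
  n <- length(block$drugs)
  mono <- lapply(seq_len(n), function(k) {
    pts <- monotherapy_points(block, block$drugs[k])
    agg <- tapply(pts$effect, match(pts$dose, block$doses[[k]]), mean)
    out <- rep(NA_real_, length(block$doses[[k]]))
    out[as.integer(names(agg))] <- as.numeric(agg)
    out
  })
  grid <- as.matrix(expand.grid(lapply(block$doses, seq_along)))
  pred <- apply(grid, 1, function(gi) {
    singles <- vapply(seq_len(n), function(k) {
      e <- mono[[k]][gi[k]]
      if (is.na(e)) 0 else e
    }, numeric(1))
    bliss_expected(singles)
  })
  predicted <- array(pred, dim = dim(A), dimnames = dimnames(A))
  predicted[is.na(A)] <- NA_real_
  list(predicted = predicted, rank = NA_integer_, method = "bliss_reference")
}

#' Flag wells that deviate from the predicted tensor
#'
#' A well is flagged as a possible outlier when its observed replicate-mean
#' inhibition deviates from the pattern-based prediction by strictly more
#' than `threshold_pp` percentage points of inhibition (default 20). The
#' report is informational: scoring honours the flags only when the user
#' opts in (`exclude_outliers` in [score_block()] / [run_synergy()]).
#'
#' @param block A `combo_block`.
#' @param prediction Result of [predict_full_tensor()]; computed on the fly
#'   if omitted.
#' @param threshold_pp Flagging threshold in percentage points.
#' @param rank_candidates,seed Passed to [predict_full_tensor()] when
#'   `prediction` is missing.
#' @return An `outlier_report`: `predicted`, `deviations_pp`, `flags`
#'   (arrays over the dose grid), `threshold_pp`, `n_flagged`.
#' @examples
#' blk <- simulate_combo_block(fixture_spec(
#'   outlier_injections = list(list(well = c(3, 4), shift = 0.3)),
#'   seed = 11))$block
#' rep <- detect_outliers(blk, seed = 1)
#' rep$n_flagged
#' @export
detect_outliers <- function(block, prediction = NULL, threshold_pp = 20,
                            rank_candidates = 1:3, seed = 1L) {
  stopifnot(inherits(block, "combo_block"))
  obs <- response_array(block)
  if (!is.null(prediction)) {
    return(flag_outliers(obs, prediction$predicted,
                         threshold_pp = threshold_pp,
                         block_id = block$block_id,
                         method = prediction$method))
  }
  # refine: wells flagged in one pass are hidden from the next factorization,
  # so a single aberrant measurement cannot drag its neighbours over threshold
  exclude <- NULL
  report <- NULL
  for (pass in 1:4) {
    prediction <- predict_full_tensor(block, rank_candidates, seed,
                                      exclude = exclude)
    report <- flag_outliers(obs, prediction$predicted,
                            threshold_pp = threshold_pp,
                            block_id = block$block_id,
                            method = prediction$method)
    if (!is.null(exclude) && identical(report$flags, exclude)) break
    if (report$n_flagged == 0) break
    exclude <- report$flags
  }
  report
}

#' @rdname detect_outliers
#' @param observed,predicted Arrays of equal shape on the fractional
#'   inhibition scale (for direct use of the rule on precomputed surfaces).
#' @param block_id,method Metadata carried into the report.
#' @export
flag_outliers <- function(observed, predicted, threshold_pp = 20,
                          block_id = NA_character_, method = "loo_nmf") {
  if (!identical(dim(observed) %||% length(observed),
                 dim(predicted) %||% length(predicted))) {
    abort("observed and predicted must have identical shape")
  }
  dev_pp <- abs(observed - predicted) * 100
  flags <- !is.na(dev_pp) & dev_pp > threshold_pp
  structure(list(block_id = block_id, predicted = predicted,
                 deviations_pp = dev_pp, flags = flags,
                 threshold_pp = threshold_pp, method = method,
                 n_flagged = sum(flags)),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> block ", x$block_id, " (", x$method, ")\n",
      "  threshold ", x$threshold_pp, " pp; ", x$n_flagged, " of ",
      sum(!is.na(x$deviations_pp)), " wells flagged\n", sep = "")
  invisible(x)
}

#' @method tidy outlier_report
#' @export
tidy.outlier_report <- function(x, ...) {
  d <- dim(x$flags)
  grid <- as.matrix(expand.grid(lapply(d, seq_len)))
  dn <- dimnames(x$flags)
  out <- tibble::as_tibble(as.data.frame(matrix(NA_real_, nrow(grid), 0)))
  for (k in seq_along(d)) {
    out[[paste0("dose_idx_", k)]] <- grid[, k]
    if (!is.null(dn)) out[[paste0("conc_", k)]] <- as.numeric(dn[[k]][grid[, k]])
  }
  out$predicted <- x$predicted[grid]
  out$deviation_pp <- x$deviations_pp[grid]
  out$outlier <- x$flags[grid]
  out$block_id <- x$block_id
  dplyr::relocate(out, "block_id")
}
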