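#' Fit a monotherapy dose-response curve
#'
#' Fits a single-drug dose-response model on the fractional inhibition scale.
#' The default is the four-parameter log-logistic (4PL) function
#' \deqn{f(x) = e_{min} + (e_{max} - e_{min}) \frac{(x/m)^\lambda}{1 + (x/m)^\lambda}}
#' where `m` is the dose producing the half-maximal effect (relative EC50 /
#' IC50 depending on readout) and `lambda` is the slope (shape) parameter.
#' LOESS and linear regression on log10 dose are available for responses that
#' do not follow the 4PL shape (e.g. U-shaped curves).
#'
#' Replicate measurements, when supplied, are pooled as additional
#' `(dose, effect)` points before fitting, so the fit on replicates equals
#' the fit on the concatenated point list.
#'
#' The 4PL fit is bounded least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}, with a bounded BFGS fallback): `e_min, e_max` in
#' `[-0.2, 1.2]`, `m` in `[min positive dose / 100, max dose * 100]`,
#' `lambda` in `[0.05, 10]`. Initialisation is deterministic: asymptotes from
#' the boundary-dose medians, `m` from the dose nearest the half-range
#' effect, `lambda = 1`. If the 4PL fit fails to converge the function falls
#' back to a linear fit with a warning, never silently.
#'
#' Dose-0 points anchor the 4PL lower asymptote but are excluded from
#' linear/LOESS fits (log10 undefined at 0).
#'
#' @param doses Numeric vector of doses (>= 0), or a data frame with columns
#'   `dose` and `effect` (tidyverse-style entry point).
#' @param effects Numeric vector of fractional inhibition values, one per
#'   dose. Ignored when `doses` is a data frame.
#' @param model One of `"4pl"`, `"linear"`, `"loess"`.
#' @param replicate_effects Optional list (or matrix, doses in rows) of extra
#'   replicate effect vectors pooled into the fit.
#' @param span LOESS span (default 0.75, degree 1).
#' @return A `dose_response_curve` object with `tidy()`, `glance()`,
#'   `predict_effect()` and `inverse_dose()` support.
#' @examples
#' crv <- fit_dose_response(c(0, 0.1, 1, 10, 100), c(0, 0.01, 0.09, 0.5, 0.91))
#' predict_effect(crv, 10)
#' inverse_dose(crv, 0.5)
#' @export
fit_dose_response <- function(doses, effects = NULL,
                              model = c("4pl", "linear", "loess"),
                              replicate_effects = NULL, span = 0.75) {
  model <- match.arg(model)
  if (is.data.frame(doses)) {
    effects <- doses$effect
    doses <- doses$dose
  }
  if (length(doses) != length(effects)) {
    abort("`doses` and `effects` must have equal length")
  }
  if (!is.null(replicate_effects)) {
    if (is.matrix(replicate_effects)) {
      replicate_effects <- as.list(as.data.frame(replicate_effects))
    }
    for (re in replicate_effects) {
      keep <- !is.na(re)
      doses <- c(doses, doses[seq_along(re)][keep])
      effects <- c(effects, re[keep])
    }
  }
  keep <- !is.na(doses) & !is.na(effects)
  doses <- doses[keep]; effects <- effects[keep]
  if (any(doses < 0)) abort("doses must be non-negative")
  n_distinct_pos <- length(unique(doses[doses > 0]))
  if (n_distinct_pos < 2) {
    abort(sprintf(
      "insufficient_data: %d distinct nonzero dose(s); at least 2 are required to fit a curve",
      n_distinct_pos), class = "combosyn_insufficient_data")
  }
  switch(model,
    "4pl"    = fit_fourpl(doses, effects),
    "linear" = fit_linear(doses, effects),
    "loess"  = fit_loess(doses, effects, span = span)
  )
}

fourpl_fun <- function(x, e_min, e_max, m, lambda) {
  p <- ifelse(x <= 0, 0, (x / m)^lambda / (1 + (x / m)^lambda))
  e_min + (e_max - e_min) * p
}

new_curve <- function(kind, params, doses, effects, fitted, converged,
                      fallback_from = NULL, extra = list()) {
  res <- effects - fitted
  structure(c(list(
    kind = kind, params = params,
    doses = doses, effects = effects,
    residual_sd = if (length(res) > 2) stats::sd(res) else 0,
    n = length(doses), converged = converged, fallback_from = fallback_from
  ), extra), class = "dose_response_curve")
}

fit_fourpl <- function(doses, effects) {
  dpos <- doses[doses > 0]
  lo <- c(e_min = -0.2, e_max = -0.2, m = min(dpos) / 100, lambda = 0.05)
  hi <- c(e_min = 1.2, e_max = 1.2, m = max(dpos) * 100, lambda = 10)
  # deterministic init: asymptotes from boundary medians, m at half-range dose
  e0 <- stats::median(effects[doses == min(doses)])
  e1 <- stats::median(effects[doses == max(doses)])
  half <- (e0 + e1) / 2
  m0 <- dpos[which.min(abs(effects[doses > 0] - half))]
  start <- pmin(pmax(c(e_min = e0, e_max = e1, m = m0, lambda = 1), lo), hi)
  dat <- data.frame(x = doses, y = effects)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fourpl_fun(x, e_min, e_max, m, lambda),
      data = dat, start = as.list(start), lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    return(new_curve("4pl", as.list(p), doses, effects,
                     fourpl_fun(doses, p["e_min"], p["e_max"], p["m"], p["lambda"]),
                     converged = TRUE))
  }
  # bounded quasi-Newton fallback on the same SSE before giving up on 4PL
  sse <- function(p) sum((effects - fourpl_fun(doses, p[1], p[2], p[3], p[4]))^2)
  opt <- tryCatch(
    stats::optim(start, sse, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL)
  if (!is.null(opt) && opt$convergence == 0) {
    p <- setNames(opt$par, names(start))
    return(new_curve("4pl", as.list(p), doses, effects,
                     fourpl_fun(doses, p["e_min"], p["e_max"], p["m"], p["lambda"]),
                     converged = TRUE))
  }
  warn("4PL fit did not converge; falling back to linear regression on log10 dose")
  out <- fit_linear(doses, effects)
  out$fallback_from <- "4pl"
  out
}

fit_linear <- function(doses, effects) {
  pos <- doses > 0
  fit <- stats::lm(y ~ x, data = data.frame(x = log10(doses[pos]), y = effects[pos]))
  cf <- stats::coef(fit)
  params <- list(intercept = unname(cf[1]),
                 slope = if (is.na(cf[2])) 0 else unname(cf[2]))
  crv <- new_curve("linear", params, doses, effects,
                   effects, converged = TRUE,
                   extra = list(dose_range = range(doses[pos])))
  crv$residual_sd <- stats::sd(stats::residuals(fit))
  crv
}

fit_loess <- function(doses, effects, span = 0.75) {
  pos <- doses > 0
  ld <- log10(doses[pos]); ef <- effects[pos]
  fit <- tryCatch(
    stats::loess(y ~ x, data = data.frame(x = ld, y = ef),
                 span = span, degree = 1,
                 control = stats::loess.control(surface = "direct")),
    error = function(e) abort(paste0("LOESS fit failed: ", conditionMessage(e))))
  grid_x <- seq(min(ld), max(ld), length.out = 101)
  grid_y <- as.numeric(predict(fit, data.frame(x = grid_x)))
  e0 <- if (any(doses == 0)) mean(effects[doses == 0]) else grid_y[1]
  fitted <- rep(e0, length(doses))
  fitted[pos] <- as.numeric(predict(fit, data.frame(x = ld)))
  new_curve("loess", list(span = span, e0 = e0), doses, effects,
            fitted, converged = TRUE,
            extra = list(grid_log10_dose = grid_x, grid_effect = grid_y))
}

#' Predict the effect of a dose from a fitted curve
#'
#' Vectorised forward evaluation of a [fit_dose_response()] curve. For the
#' 4PL model, dose 0 gives `e_min`, dose `m` the midpoint, and the effect
#' approaches `e_max` as the dose grows.
#'
#' @param curve A `dose_response_curve`.
#' @param dose Numeric vector of doses (>= 0).
#' @return Numeric vector of fractional inhibition values.
#' @export
predict_effect <- function(curve, dose) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (any(dose < 0, na.rm = TRUE)) abort("doses must be non-negative")
  p <- curve$params
  switch(curve$kind,
    "4pl" = fourpl_fun(dose, p$e_min, p$e_max, p$m, p$lambda),
    "linear" = {
      out <- p$intercept + p$slope * log10(pmax(dose, .Machine$double.xmin))
      out[dose == 0] <- p$intercept + p$slope * log10(curve$dose_range[1] / 100)
      out
    },
    "loess" = {
      out <- stats::approx(curve$grid_log10_dose, curve$grid_effect,
                           xout = log10(pmax(dose, .Machine$double.xmin)),
                           rule = 2)$y
      out[dose == 0] <- p$e0
      out
    })
}

#' Invert a fitted curve: which dose produces a given effect?
#'
#' Solves `predict_effect(curve, x) = effect` for `x`. This is the
#' dose-of-equal-effect lookup that the Loewe additivity model needs: the
#' doses of the single drugs required to produce the combination effect.
#'
#' For 4PL and linear curves the inverse is closed-form and exact. LOESS
#' curves are inverted by bracketed root search on the smoothed grid and
#' raise an error if the smooth is non-monotone around the target effect.
#'
#' Effects outside the curve's achievable open interval return `NA_real_`
#' (the "unreachable" sentinel): no finite dose of this drug alone produces
#' that effect.
#'
#' @param curve A `dose_response_curve`.
#' @param effect Numeric vector of fractional inhibition targets.
#' @return Numeric vector of doses; `NA_real_` where unreachable.
#' @export
inverse_dose <- function(curve, effect) {
  stopifnot(inherits(curve, "dose_response_curve"))
  p <- curve$params
  switch(curve$kind,
    "4pl" = {
      lohi <- sort(c(p$e_min, p$e_max))
      r <- (effect - p$e_min) / (p$e_max - effect)
      out <- p$m * r^(1 / p$lambda)
      out[effect <= lohi[1] | effect >= lohi[2]] <- NA_real_
      out
    },
    "linear" = {
      if (p$slope == 0) return(rep(NA_real_, length(effect)))
      10^((effect - p$intercept) / p$slope)
    },
    "loess" = vapply(effect, invert_loess, numeric(1), curve = curve))
}

invert_loess <- function(curve, effect) {
  gy <- curve$grid_effect; gx <- curve$grid_log10_dose
  lohi <- range(gy)
  if (effect <= lohi[1] || effect >= lohi[2]) return(NA_real_)
  cross <- which(diff(sign(gy - effect)) != 0)
  if (length(cross) == 0) return(NA_real_)
  if (length(cross) > 1) {
    abort("LOESS curve is non-monotone around the target effect; not invertible",
          class = "combosyn_not_invertible")
  }
  i <- cross[1]
  f <- function(lx) stats::approx(gx, gy, xout = lx)$y - effect
  10^stats::uniroot(f, c(gx[i], gx[i + 1]), tol = 1e-12)$root
}

# achievable effect interval of a curve (open), used by the Loewe solver
curve_effect_range <- function(curve) {
  p <- curve$params
  switch(curve$kind,
    "4pl" = sort(c(p$e_min, p$e_max)),
    "linear" = {
      if (p$slope == 0) return(c(p$intercept, p$intercept))
      sort(p$intercept + p$slope *
             log10(c(curve$dose_range[1] / 100, curve$dose_range[2] * 100)))
    },
    "loess" = range(curve$grid_effect))
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat("<dose_response_curve> ", x$kind, ", n = ", x$n, "\n", sep = "")
  if (x$kind == "4pl") {
    with(x$params, cat(sprintf(
      "  e_min = %.4g, e_max = %.4g, m = %.4g, lambda = %.4g\n",
      e_min, e_max, m, lambda)))
  }
  cat(sprintf("  residual SD = %.4g\n", x$residual_sd))
  invisible(x)
}

#' @method tidy dose_response_curve
#' @export
tidy.dose_response_curve <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = unlist(x$params, use.names = FALSE))
}

#' @method glance dose_response_curve
#' @export
glance.dose_response_curve <- function(x, ...) {
  tibble::tibble(kind = x$kind, n = x$n, residual_sd = x$residual_sd,
                 converged = x$converged,
                 fallback_from = x$fallback_from %||% NA_character_)
}

#' @method autoplot dose_response_curve
#' @export
autoplot.dose_response_curve <- function(object, n_grid = 120, ...) {
  dpos <- object$doses[object$doses > 0]
  grid <- 10^seq(log10(min(dpos)) - 0.5, log10(max(dpos)) + 0.5,
                 length.out = n_grid)
  fit_df <- tibble::tibble(dose = grid, effect = predict_effect(object, grid))
  obs_df <- tibble::tibble(dose = object$doses, effect = object$effects)
  ggplot2::ggplot(fit_df, ggplot2::aes(x = .data$dose, y = .data$effect)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(data = obs_df[obs_df$dose > 0, ]) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "fractional inhibition") +
    ggplot2::theme_minimal()
}
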