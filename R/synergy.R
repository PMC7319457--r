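#' Dose-wise synergy under the four reference models
#'
#' Each reference model predicts the combination effect expected if the
#' drugs did not interact; the dose-wise synergy score is the measured
#' combination effect minus that expectation (positive = synergy,
#' negative = antagonism), on the fractional inhibition scale.
#'
#' * **HSA** (highest single agent): expected = `max(single_effects)`.
#' * **Bliss** independence: expected = probabilistic union of the single
#'   effects treated as independent events,
#'   `1 - prod(1 - E_i)` (equivalently the inclusion-exclusion sum
#'   `sum E_i - sum E_i E_j + ...`). Single effects are clamped to `[0, 1]`
#'   inside the product, where independence is defined.
#' * **Loewe** additivity ([loewe_expected()]): the expected effect `y`
#'   solves `sum_i d_i / D_i(y) = 1`, where `D_i(y)` is the dose of drug `i`
#'   alone producing effect `y` (a sham combination of a drug with itself is
#'   exactly additive).
#' * **ZIP** (zero interaction potency, [zip_expected()]): independence
#'   applied to the fitted log-logistic potency terms
#'   `p_i = (x_i/m_i)^lambda_i / (1 + (x_i/m_i)^lambda_i)`, i.e. the drugs
#'   are assumed not to shift each other's potency.
#'
#' @param e_combo Measured combination effect (fractional inhibition).
#' @param single_effects Numeric vector (length >= 2 for a combination; >= 1
#'   accepted for sub-expressions) of measured monotherapy effects at the
#'   combination's component doses.
#' @return The dose-wise synergy score (scalar).
#' @examples
#' hsa_score(0.8, c(0.5, 0.6)) # 0.2
#' bliss_score(0.875, c(0.5, 0.5, 0.5)) # exactly independent -> 0
#' @export
hsa_score <- function(e_combo, single_effects) {
  if (length(single_effects) == 0) abort("single_effects must be non-empty")
  e_combo - max(single_effects)
}

#' @rdname hsa_score
#' @export
bliss_score <- function(e_combo, single_effects) {
  e_combo - bliss_expected(single_effects)
}

#' @rdname hsa_score
#' @export
bliss_expected <- function(single_effects) {
  if (length(single_effects) == 0) abort("single_effects must be non-empty")
  e <- pmin(pmax(single_effects, 0), 1)
  1 - prod(1 - e)
}

#' Expected combination effect under Loewe additivity
#'
#' Solves the Loewe additivity condition
#' \deqn{\sum_i \frac{d_i}{D_i(y)} = 1}
#' for the expected effect `y`, where `d_i` are the component doses and
#' `D_i(y) =` [inverse_dose()] of drug `i`'s fitted curve. The left-hand
#' side is strictly decreasing in `y` over the achievable effect interval,
#' so the root is found by bisection (tolerance 1e-12 in effect units).
#'
#' Effects a drug cannot reach on its own contribute dose-ratio 0 (the
#' required dose is infinite), so the expected response is capped at the
#' most efficacious single agent's asymptote: if the additivity sum still
#' exceeds 1 there, that boundary effect is returned.
#'
#' @param component_doses Positive doses, one per drug.
#' @param curves List of fitted `dose_response_curve` objects, one per drug
#'   (must be invertible; LOESS curves that are non-monotone raise an error).
#' @return The expected fractional inhibition `y`. The dose-wise Loewe
#'   synergy score is `measured - y`.
#' @examples
#' crv <- fit_dose_response(c(0, 1, 3, 10, 30, 100),
#'                          fourpl_effect(c(0, 1, 3, 10, 30, 100), 0, 1, 10, 1))
#' # sham combination: 5 + 5 of the same drug behaves like 10
#' loewe_expected(c(5, 5), list(crv, crv))
#' predict_effect(crv, 10)
#' @export
loewe_expected <- function(component_doses, curves) {
  stopifnot(length(component_doses) == length(curves), length(curves) >= 1)
  if (any(component_doses <= 0)) abort("component doses must be positive")
  ranges <- lapply(curves, curve_effect_range)
  y_lo <- max(vapply(ranges, `[`, numeric(1), 1))
  y_hi <- max(vapply(ranges, `[`, numeric(1), 2))
  if (!(y_hi > y_lo)) {
    abort("no curve has a usable effect range; Loewe model unavailable",
          class = "combosyn_model_unavailable")
  }
  eps <- (y_hi - y_lo) * 1e-12
  g <- function(y) {
    total <- 0
    for (i in seq_along(curves)) {
      D <- suppressWarnings(inverse_dose(curves[[i]], y))
      if (is.na(D)) {
        # above this drug's reach -> infinite dose needed -> ratio 0;
        # below its floor -> zero dose suffices -> ratio +Inf
        if (y <= ranges[[i]][1]) return(Inf)
      } else {
        total <- total + component_doses[i] / D
      }
    }
    total
  }
  if (g(y_hi - eps) >= 1) return(y_hi)
  if (g(y_lo + eps) <= 1) return(y_lo)
  lo <- y_lo + eps; hi <- y_hi - eps
  for (iter in 1:100) {
    mid <- (lo + hi) / 2
    if (g(mid) > 1) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

# auxiliary combination-index sum at the measured effect, exported in tables
loewe_ci_sum <- function(component_doses, curves, measured) {
  total <- 0
  for (i in seq_along(curves)) {
    D <- suppressWarnings(inverse_dose(curves[[i]], measured))
    if (is.na(D)) return(NA_real_)
    total <- total + component_doses[i] / D
  }
  total
}

#' Expected combination effect under zero interaction potency (ZIP)
#'
#' The ZIP reference assumes the drugs do not shift each other's potency:
#' each drug contributes its fitted log-logistic potency term
#' `p_i = (x_i/m_i)^lambda_i / (1 + (x_i/m_i)^lambda_i)` and the expected
#' combination effect is their probabilistic union `1 - prod(1 - p_i)`.
#' Only the fitted midpoint `m` and slope `lambda` enter; the canonical
#' 0-to-1 logistic is used regardless of the fitted asymptotes.
#'
#' @param component_doses Doses, one per drug (dose 0 contributes `p = 0`).
#' @param curves List of fitted 4PL `dose_response_curve` objects. Other
#'   curve kinds raise a model-unavailable error.
#' @return Expected fractional inhibition. The dose-wise ZIP synergy score
#'   is `measured - expected`.
#' @export
zip_expected <- function(component_doses, curves) {
  stopifnot(length(component_doses) == length(curves))
  p <- vapply(seq_along(curves), function(i) {
    crv <- curves[[i]]
    if (!inherits(crv, "dose_response_curve") || crv$kind != "4pl") {
      abort("ZIP requires a fitted 4PL curve for every drug",
            class = "combosyn_model_unavailable")
    }
    x <- component_doses[i]
    if (x <= 0) return(0)
    t <- (x / crv$params$m)^crv$params$lambda
    t / (1 + t)
  }, numeric(1))
  1 - prod(1 - p)
}

#' Evaluate the 4PL function directly
#'
#' Convenience for building known-truth dose-response values:
#' `e_min + (e_max - e_min) * (x/m)^lambda / (1 + (x/m)^lambda)`.
#'
#' @param dose Numeric vector of doses (>= 0).
#' @param e_min,e_max Lower (dose 0) and upper (asymptotic) effects.
#' @param m Dose of half-maximal effect.
#' @param lambda Slope (shape) parameter.
#' @export
fourpl_effect <- function(dose, e_min, e_max, m, lambda) {
  fourpl_fun(dose, e_min, e_max, m, lambda)
}

#' Enumerate all scoreable sub-combinations
#'
#' Every subset of 2..N drugs from a higher-order combination is scored
#' separately (pairs, triplets, ...), to attribute each drug's contribution
#' to the joint response. Subsets are ordered by size, then
#' lexicographically.
#'
#' @param drugs Character vector of drug names (N >= 2).
#' @return List of character vectors.
#' @examples
#' enumerate_subcombinations(c("A", "B", "C"))
#' @export
enumerate_subcombinations <- function(drugs) {
  n <- length(drugs)
  if (n < 2) abort("a combination needs at least 2 drugs")
  out <- list()
  for (size in 2:n) {
    combos <- utils::combn(drugs, size, simplify = FALSE)
    ord <- order(vapply(combos, paste, character(1), collapse = "\r"))
    out <- c(out, combos[ord])
  }
  out
}
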