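#' Convert percent readouts to fractional inhibition
#'
#' All internal computation in combosyn happens on the fractional inhibition
#' scale (0 = no effect, 1 = complete inhibition), because the Bliss and ZIP
#' reference models multiply probability-like effects. Input files carry
#' percent values; this helper maps them onto the internal scale:
#' `% inhibition x` becomes `x / 100` and `% viability v` becomes
#' `(100 - v) / 100`.
#'
#' Values outside the 0--100% range (over-growth, super-maximal inhibition)
#' are preserved, not clamped; a single warning reports how many such values
#' were seen. Clamping to `[0, 1]` happens only inside the Bliss/ZIP expected
#' term, where products are otherwise undefined.
#'
#' @param values Numeric vector of percent-scale readouts.
#' @param readout Either `"inhibition"` or `"viability"`.
#' @return Numeric vector of fractional inhibition values.
#' @examples
#' normalize_readout(c(0, 50, 100), "inhibition")
#' normalize_readout(100, "viability") # untreated control -> 0
#' @export
normalize_readout <- function(values, readout = c("inhibition", "viability")) {
  readout <- match.arg(readout)
  if (!is.numeric(values)) abort("readout values must be numeric (percent scale)")
  out <- if (readout == "inhibition") values / 100 else (100 - values) / 100
  n_off <- sum(out < 0 | out > 1, na.rm = TRUE)
  if (n_off > 0) {
    warn(sprintf("%d response value(s) fall outside the 0-100%% range; kept as-is", n_off))
  }
  out
}
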