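# Shared test helpers: exact curve objects and small hand-built blocks.

# a dose_response_curve with exactly known 4PL parameters (no fitting noise)
exact_curve <- function(e_min = 0, e_max = 1, m = 1, lambda = 1) {
  doses <- c(0, m * 10^seq(-2, 2, length.out = 9))
  structure(list(
    kind = "4pl",
    params = list(e_min = e_min, e_max = e_max, m = m, lambda = lambda),
    doses = doses,
    effects = fourpl_effect(doses, e_min, e_max, m, lambda),
    residual_sd = 0, n = length(doses), converged = TRUE,
    fallback_from = NULL), class = "dose_response_curve")
}

# brute-force inclusion-exclusion union of effects: sum over all nonempty
# subsets of (-1)^(|T|+1) prod(E_T) -- the expanded reference formula
union_by_expansion <- function(e) {
  n <- length(e)
  total <- 0
  for (size in seq_len(n)) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      total <- total + (-1)^(size + 1) * prod(e[idx])
    }
  }
  total
}

# long-format wells for a tiny 2-drug block (percent inhibition responses)
tiny_table_df <- function(block_id = "b1") {
  g <- expand.grid(conc_1 = c(0, 1, 10), conc_2 = c(0, 1, 10))
  data.frame(block_id = block_id, drug_1 = "A", drug_2 = "B",
             conc_1 = g$conc_1, conc_2 = g$conc_2,
             response = ifelse(g$conc_1 > 0, 10 * log10(g$conc_1 * 10), 0) +
               ifelse(g$conc_2 > 0, 15 * log10(g$conc_2 * 10), 0),
             conc_unit_1 = "uM", conc_unit_2 = "uM")
}

# partial-design block: one nonzero dose per drug plus monotherapy anchors
partial_block <- function() {
  df <- data.frame(
    block_id = "p1", drug_1 = "A", drug_2 = "B",
    conc_1 = c(0, 5, 0, 5), conc_2 = c(0, 0, 2, 2),
    response = c(0, 30, 40, 80))
  as_combo_block(df)
}
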