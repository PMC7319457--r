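# combosyn

Synergy scoring for multi-drug dose–response combination screens.

High-throughput combination screening measures the response (% inhibition
or % viability) of cells treated with every dose combination of two or
more drugs. A combination is *synergistic* when the measured joint effect
exceeds what a no-interaction reference model predicts from the
monotherapy responses, and *antagonistic* when it falls short. `combosyn`
scores N-drug (N ≥ 2) dose–response tensors under the four standard
reference models and reports dose-wise and summary synergy for every
sub-combination of drugs (pairs, triplets, …), with replicate statistics,
automated outlier flagging, static visual summaries, exportable tables
and a command-line entry point.

## The reference models

Writing `E_A, E_B, …` for the measured single-drug effects (fractional
inhibition) at the combination's component doses and `E_{A,B,…,N}` for the
measured combination effect, the dose-wise synergy score under each model
is the measured effect minus the expected effect:

* **HSA** (highest single agent): expected = `max(E_A, …, E_N)`.
* **Bliss** independence: expected = `1 − ∏ᵢ (1 − Eᵢ)`, the probabilistic
  union of independent single-drug effects (equivalently the
  inclusion–exclusion sum `ΣEᵢ − ΣEᵢEⱼ + …`).
* **Loewe** additivity: expected effect `y` solves `Σᵢ dᵢ / Dᵢ(y) = 1`,
  where `dᵢ` is the dose of drug *i* in the well and `Dᵢ(y)` the dose of
  drug *i* alone producing effect `y` (from its fitted curve). A drug
  combined with itself ("sham combination") is exactly additive.
* **ZIP** (zero interaction potency): expected =
  `1 − ∏ᵢ (1 − pᵢ)` with `pᵢ = (xᵢ/mᵢ)^λᵢ / (1 + (xᵢ/mᵢ)^λᵢ)` from each
  drug's fitted four-parameter log-logistic (4PL) curve — the drugs are
  assumed not to shift each other's potency (midpoint `m`, slope `λ`).

Monotherapy curves are fitted with the 4PL function by default
(`f(x) = e_min + (e_max − e_min)(x/m)^λ / (1 + (x/m)^λ)`), with LOESS and
log-linear regression as alternatives; replicates are pooled into the fit.
The per-combination *summary score* is the mean of the dose-wise scores
over all measured (optionally non-outlier) wells, with a replicate-based
standard deviation.

Outlier wells are flagged by predicting the full dose–response tensor
from its overall pattern (leave-one-out non-negative matrix completion)
and marking wells whose observed inhibition deviates from the prediction
by more than 20 percentage points.

Inputs arrive in two dialects — **Table** (long format, one row per well,
any number of drugs) and **Matrix** (one wide dose–response grid per
block, two drugs) — as CSV/TSV/XLSX, in % inhibition or % viability. Both
full designs (multiple doses per drug) and partial designs (some drug at
a single fixed dose) are accepted; partial designs support only the HSA
and Bliss scores, because Loewe and ZIP need fitted curves.

## Worked example

```r
library(combosyn)

# simulate a 2-drug screen: Bliss-null interior + 0.12 planted synergy,
# 3 replicates with noise SD 0.04, and write it as a Table-dialect file
spec <- fixture_spec(n_drugs = 2,
  curves = list(list(e_min = 0, e_max = 1,   m = 1, lambda = 1),
                list(e_min = 0, e_max = 0.9, m = 5, lambda = 1.5)),
  synergy_offset = 0.12, noise_sd = 0.04, n_replicates = 3, seed = 7)
fx <- simulate_combo_block(spec, block_id = "demo")
write_combo_file(fx$block, "demo_combo.csv")

blk <- read_combo_table("demo_combo.csv")[[1]]
blk
#> <combo_block> demo: A + B
#>   grid 6 x 6 (doses incl. 0), 108 measurements, design = full

rep <- detect_outliers(blk, seed = 1)
rep
#> <outlier_report> block demo (loo_nmf)
#>   threshold 20 pp; 0 of 36 wells flagged

res <- score_block(blk, outlier_report = rep)
summarize_synergy(res)
#> # A tibble: 4 x 7
#>   block_id drug_subset subset_size model summary_score      sd n_wells
#> 1 demo     A+B                   2 HSA          0.199  0.00829      25
#> 2 demo     A+B                   2 Bliss        0.133  0.00829      25
#> 3 demo     A+B                   2 Loewe        0.162  0.00829      25
#> 4 demo     A+B                   2 ZIP          0.0937 0.00829      25
```

The Bliss summary (0.133 ± 0.008 over 25 interior wells) recovers the
planted 0.12 offset within replicate noise; HSA reads higher because the
Bliss expectation always exceeds the best single agent. `tidy(res)` gives
the per-well scores, `autoplot()` on a surface draws the synergy
heatmap, `plot_subcombination_bars()` the summary barplot, and
`build_report()` assembles a self-contained HTML report with a
machine-readable CSV bundle.

The same pipeline runs from the shell:

```sh
combosyn=$(Rscript -e 'cat(system.file("scripts", "combosyn", package = "combosyn"))')
Rscript "$combosyn" fixtures --out demo_combo.csv --noise-sd 0.04 --seed 7
Rscript "$combosyn" score --input demo_combo.csv --out results_dir --report-style dynamic-data
```

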