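---
title: "Scoring multi-drug combination screens with combosyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring multi-drug combination screens with combosyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combosyn)
```

## The scoring model

A combination screen measures a response — % inhibition of cell growth,
or % viability — over the Cartesian product of per-drug dose ladders,
each ladder including dose 0. `combosyn` stores this as a dose–response
tensor on the *fractional inhibition* scale (inhibition `x%` is `x/100`;
viability `v%` is `(100 − v)/100`). The fractional scale is not
cosmetic: the Bliss and ZIP models multiply effects as if they were
probabilities of independent events, which is only coherent on `[0, 1]`.
Measured values outside that range (over-growth, super-maximal
inhibition) are preserved everywhere and clamped only inside those
products.

For a well with component doses $d_1,\dots,d_N$ (all $> 0$), measured
combination effect $E_{1\ldots N}$, and measured single-drug effects
$E_i$ at the same doses, the dose-wise synergy score under every model is

$$S = E_{1\ldots N} - E_{\mathrm{expected}},$$

with the expectation given by the model:

* **HSA**: $\max_i E_i$.
* **Bliss**: $1 - \prod_i (1 - E_i)$, equal to the inclusion–exclusion
  sum $\sum E_i - \sum_{i<j} E_i E_j + \dots$ (asserted to $10^{-12}$ in
  the tests for up to five drugs).
* **Loewe**: the $y$ solving $\sum_i d_i / D_i(y) = 1$, where $D_i(y)$
  inverts drug $i$'s fitted monotherapy curve.
* **ZIP**: $1 - \prod_i (1 - p_i)$ with
  $p_i = (d_i/m_i)^{\lambda_i} / (1 + (d_i/m_i)^{\lambda_i})$ from the
  fitted 4PL parameters.

Reporting all four models on the same response-difference scale keeps
dose-wise maps and summary averages comparable across models. The Loewe
condition is classically stated as a combination index (the additivity
sum itself); we solve it for the expected response and difference it like
the other models, and export the raw sum at the measured effect as an
auxiliary `loewe_ci` column (values below 1 indicate synergy on that
scale). One textual convention is worth flagging: descriptions of the
additivity equation sometimes read as if the numerators were the doses
producing the combination effect; the implementation follows the standard
Loewe equation, with the well's component doses in the numerators and the
equally-effective single-drug doses in the denominators.

Every subset of $\ge 2$ drugs is scored separately over its own interior
wells (all subset doses $> 0$, all remaining drugs at dose 0), so a
triplet yields scores for three pairs and the triplet itself — the
sub-combination census for $N$ drugs is $2^N - N - 1$. The summary score
of a subset is the arithmetic mean of its dose-wise scores over measured,
non-masked wells.

### HSA/Bliss use measured monotherapies; Loewe/ZIP use fitted curves

HSA and Bliss only need the measured monotherapy wells (replicate means),
so they work on *partial* designs where some drug has a single fixed
dose. Loewe and ZIP need a fitted, invertible curve per drug and
therefore refuse partial designs with an explicit error rather than
silently extrapolating from one point.

## Curve fitting

The default monotherapy model is the four-parameter log-logistic

$$f(x) = e_{min} + (e_{max} - e_{min})
  \frac{(x/m)^{\lambda}}{1 + (x/m)^{\lambda}},$$

fitted by bounded least squares (Levenberg–Marquardt, with a bounded
L-BFGS-B retry on failure). The bounds —
$e_{min}, e_{max} \in [-0.2, 1.2]$, $m$ within two decades of the
measured dose range, $\lambda \in [0.05, 10]$ — exist to stop asymptotes
and midpoints running away on truncated ladders; they are wide enough
never to bind on well-behaved data. Initialisation is deterministic
(boundary-dose medians for the asymptotes, the dose nearest the
half-range effect for $m$, $\lambda = 1$), so fits are reproducible and
order-invariant. If the 4PL fit fails outright the function falls back to
log-linear regression with a warning, never silently. Replicates are
pooled as extra points, which is definitionally the fit on the
concatenated point list.

LOESS (span 0.75, degree 1, on log10 dose) accommodates non-monotone,
e.g. U-shaped, responses. A non-monotone fit has no single inverse; since
Loewe requires inversion, inverting a LOESS curve that is non-monotone
around the target effect raises an explicit error instead of picking a
branch. Dose-0 points anchor the 4PL lower asymptote but are excluded
from linear/LOESS fits (log of zero).

Curve inversion is closed-form for 4PL and linear; effects outside a
curve's open achievable interval return the unreachable sentinel
(`NA`). The Loewe solver treats unreachable effects as contributing zero
dose-ratio (an infinite dose would be needed), so the expected response
is capped by the most efficacious single agent's range. Because the
additivity sum is strictly decreasing in $y$, the solver is a plain
bisection (100 iterations, interval $10^{-12}$); the tests verify it
against a dense-grid root search to $10^{-6}$ effect units.

## Outlier detection

Screens contain sporadic aberrant wells (dispense failures, edge
effects). Rather than judging wells against their own replicates only,
`combosyn` predicts every well from the *overall pattern* of the tensor:
the replicate-mean tensor is matricized (first drug's ladder as rows,
remaining axes flattened), negative inhibitions are clamped to 0, and a
non-negative matrix factorization is fitted with the well of interest
masked, so each well's prediction never sees its own value. The
factorization rank is chosen from {1, 2, 3} by cross-validation on a
seeded 20% holdout of observed cells. A Bliss-additive two-drug surface
is exactly non-negative rank 2 ($E = u \otimes 1 + (1-u) \otimes v$), so
low ranks capture realistic smooth tensors while a rank that could
memorise single wells is never offered.

A well is flagged when its observed replicate-mean inhibition deviates
from the prediction by strictly more than 20 percentage points. Two
readings of "20%" are possible — relative to the measured level, or
absolute percentage points; the absolute reading is implemented, as the
relative one would make the rule explode near zero inhibition. Flagged
wells are then hidden from the factorization and the remaining wells
re-flagged (up to four passes), so a single large outlier cannot drag its
neighbours over threshold; this also makes the flags stable under
permutation of the drug axes. Predictions are clamped to $[0, 1]$ —
an extrapolation outside the inhibition scale is never evidence against
a well. Tensors with fewer than three doses on some ladder carry too
little pattern for completion and fall back to a smooth reference
surface (the Bliss expectation of the measured monotherapies); wells in
slices with no observations get no prediction and are never flagged.

Flagging is always reported; it only affects the summary averages when
the user opts in (`exclude_outliers`), since genuine strong synergy
pockets can also deviate from a low-rank pattern.

The NMF stand-in sits behind the single `predict_full_tensor()`
interface, so a different matrix-completion predictor can be swapped in
without touching the flagging rule.

## Replicate statistics

Curves are fitted on pooled replicates; each replicate is then scored
against the shared expected surface. The per-well `replicate_sd` is the
standard deviation of the replicate-wise scores (absent, not zero, for
singly-measured wells); the summary SD is the standard deviation of the
per-replicate summary means. Because the expectation is shared, the
replicate spread of the scores equals the replicate spread of the
measurements, which is what the SD is meant to convey.

## The fixture generator

`fixture_spec()` / `simulate_combo_block()` generate tensors with known
ground truth: monotherapy slices drawn from stated 4PL curves, interior
wells from a declared null model (Bliss, HSA, Loewe-sham, or ZIP), an
optional additive synergy offset on the interior (optionally
region-restricted), seeded Gaussian replicate noise truncated to
$[-0.2, 1.2]$, and single-well outlier injections applied last. Defaults
emulate a routine screen: six-point ladders (dose 0 plus five half-log
steps spanning the midpoint), unit midpoints, Hill slope 1, full effect
window, no noise. Fixture curves must have $e_{min} = 0$ — untreated
cells show no inhibition — which also makes the Bliss and ZIP nulls
coincide, and the Loewe-sham null requires all drugs to share one curve
(that *is* the sham construction).

With zero noise and no offset the generated tensor satisfies its null
exactly, so the matching score is zero to machine precision — the
closed-loop property the test suite leans on. The ZIP null is only exact
for curves with asymptotes 0 and 1, because the printed ZIP expectation
uses the canonical 0-to-1 logistic regardless of fitted asymptotes;
whether the ZIP term should be rescaled by $e_{min}/e_{max}$ is a known
ambiguity, and the un-rescaled form is implemented. Likewise the
original bidirectional ZIP formulation (averaging potency shifts fitted
in both directions) is intentionally not implemented; the product of
fitted monotherapy logistic terms is.

What the generator does *not* emulate: plate-positional artifacts
(edge/drift effects), correlated noise between neighbouring wells,
biphasic monotherapies, or dose-dependent variance. Tests passing on
fixtures therefore demonstrate correctness of the scoring machinery and
its statistical conventions, not robustness to every real-plate
pathology.

## Numerical conventions and degenerate inputs

* Bisection tolerance $10^{-12}$ in effect units; curve inversion is
  exact (closed form) for 4PL/linear and $10^{-12}$ root tolerance for
  LOESS grids.
* NMF: multiplicative updates, up to 2000 iterations, relative objective
  tolerance $10^{-12}$ checked every 25 iterations, seed-controlled
  uniform initialisation; the user seed fixes holdout and init, making
  runs bit-reproducible.
* Wells measured repeatedly are always replicates; there is no
  "last value wins".
* Dose ladders must include 0 (or a labelled control) because every
  reference model needs monotherapy anchors; a missing dose-0 ladder is
  a schema error, not a warning.
* A subset whose wells are all masked raises an empty-summary error
  rather than returning NaN.
* A 1×1 interior grid (partial design) renders as a single labelled
  cell, not an error.
* Ties in model ordering are resolved by the fixed order HSA, Bliss,
  Loewe, ZIP in every table and report.

## Problem sizes

The shipped tests and the acceptance script run on 6×6×(replicates)
two-drug grids, 4×4 ladders for three- and four-drug blocks, 20-seed
batteries for stochastic checks, and dense grids of $2 \times 10^6$
points for the Loewe root-search oracle — sizes chosen so the full
battery represents each study condition faithfully while completing in a
few minutes on a single core.

## Known limitations

* The Loewe solver assumes monotone fitted curves; true non-monotone
  pharmacology needs a different additivity formulation.
* ZIP requires 4PL fits; LOESS/linear monotherapies exclude ZIP.
* The matrix-dialect reader handles two drugs per block; higher-order
  data must use the table dialect.
* The outlier predictor is a generic matrix-completion stand-in behind a
  stable interface, not a trained screening-specific model; its flags
  are advisory.
* No p-values beyond replicate SDs are computed; with ≤ 3 replicates a
  formal test would be weaker than the reported spread.
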