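---
title: "Comparing LDL cholesterol estimating equations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing LDL cholesterol estimating equations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlconcord)
```

## The problem

Calculated LDL cholesterol is the workhorse of cardiovascular risk
management. The Friedewald formula (FF) estimates the cholesterol
carried in VLDL particles as TG/2.2 (mmol/L) — equivalently TG/5 in
mg/dL by its historical convention — i.e. it assumes a *fixed*
triglyceride:VLDL-cholesterol mass ratio. Physiologically that ratio is
not fixed: it runs from roughly 5 to 9, rising with TG as large,
triglyceride-rich VLDL1 particles come to dominate. FF therefore
increasingly *under*-estimates LDL-C as TG rises, precisely in the
patients whose classification near the 1.81 mmol/L primary-prevention
threshold decides whether statin therapy is offered. The Martin-Hopkins
(MH) equation replaces the fixed divisor by a factor looked up from a
TG × non-HDL-C stratification; the Sampson-NIH equation absorbs the same
physiology into a bivariate quadratic. This package implements all
three, the concordance analysis that quantifies their clinical
disagreement, and a synthetic cohort with known ground truth on which
every stage is testable.

## Equations and numerical conventions

- **Canonical units.** FF and Sampson-NIH are specified in mmol/L and
  computed there; MH is specified in mg/dL and computed there. Panels in
  either unit system are converted on the way in and results are
  returned in the caller's units. Conversion constants are fixed at
  38.67 (cholesterol) and 88.57 (TG) mg/dL per mmol/L. A consequence
  worth noting: FF's mmol/L divisor 2.2 corresponds to a mass ratio of
  2.2·88.57/38.67 = 5.039, not exactly 5; tests that reason about "the
  fixed ratio 5" account for this.
- **Validity ranges.** FF returns no value at TG ≥ 4.52 mmol/L (the
  boundary itself is excluded). Sampson-NIH and extended-mode MH reach
  TG ≤ 9.04 mmol/L; original-mode MH stops above 4.51 mmol/L. Records
  with TG > 9.04 mmol/L are excluded from the analysis entirely.
- **Negative estimates** are returned and flagged
  (`NEGATIVE_ESTIMATE`), never clamped — auditability over tidiness.
  Downstream category assignment maps them to the lowest band.
- **MH factor lookup.** Cells are half-open, lower-bound inclusive;
  inputs beyond the outermost boundary use the outermost cell (the
  published top strata are open-ended). The packaged table is a 30 × 6
  (180-cell) transcription of the 2013 median-factor table, factors
  3.1–11.9. Two caveats are deliberately surfaced in its provenance
  string: (i) the transcription could not be re-verified against the
  original supplement when packaged, so individual cells may deviate —
  it must be checked before clinical use, and every quantitative test in
  this package runs on small synthetic tables or the constant-factor
  table instead; (ii) descriptions of the stratification's size vary
  between sources (a 240-cell variant is sometimes described); the
  packaged dimensions follow the transcription source. The table is
  fully pluggable (`read_mh_table()`), which is also how a laboratory
  would drop in the 2021 extended table; the `extended` flag as shipped
  only widens the validity range, reusing the open-ended top TG stratum.
- **Quartiles.** All medians/IQRs use linear-interpolation (type-7)
  quantiles, and IQR is reported as the single width Q3 − Q1.
- **Wilcoxon signed-rank** drops zero differences, mid-ranks ties, and
  uses the normal approximation with tie correction and no continuity
  correction (it matches `stats::wilcox.test(exact = FALSE,
  correct = FALSE)` exactly; that stock routine is the independent
  oracle in the tests, keeping the dual-route check honest).
- **Category and TG-stratum intervals** are half-open, lower-inclusive,
  at full precision in mmol/L: the printed two-decimal ranges
  ("1.81–2.56" followed by "2.57–3.34") imply boundaries at 1.81, 2.57,
  …, not at rounded mg/dL equivalents. TG 9.04 closes the final
  stratum.

## The percentage-difference sign convention

Sources are genuinely ambiguous about what "A − B (percentage
difference)" denominates, and the sign pattern matters clinically. This
package fixes one convention and prints it in every summary: for a pair
(reference, comparator), the stratified tables report
`100·(comparator − reference)/reference`. For (FF, MH) this runs from
negative at low TG (the adjustable factor sits below FF's implied ratio,
so MH reads lower) through zero near TG ≈ 1.1–1.3 mmol/L to strongly
positive at high TG (FF under-estimates). `percent_difference()` itself
is the low-level primitive `100·(a − b)/denom` with the denominator
configurable (`"second"`, `"first"`, `"mean"`). Published tables that
mix conventions across column pairs cannot be matched sign-for-sign by
any single rule; we chose uniformity and documentation over mimicry.

## The synthetic world

The generator emulates the *marginal* structure of a large private-lab
cohort and the *mechanism* under study, not any individual dataset:

- **Marginals.** Sex split 43.05% female; per-sex TG medians/IQRs
  0.89/0.54 (F) and 1.02/0.71 (M) mmol/L; HDL 1.45/0.46 and 1.24/0.39;
  true-LDL 3.10/1.42 overall (the source reports only an overall
  calculated-LDL distribution, used here as the truth target — the
  simulation is self-consistent, not a population claim). Age bands at
  the cohort's per-sex frequencies (18–24 … 65–75), uniform within
  band; visit dates uniform over 2019-01-01..2023-12-31.
- **Marginal family.** Log-normal for TG, HDL and LDL: positive,
  right-skewed, and exactly parameterizable from a median and IQR via
  the closed form `sdlog = asinh(iqr/(2·median))/qnorm(0.75)` (the
  quartile equation `iqr = 2·median·sinh(z·sdlog)` inverts
  analytically, so no numeric root-find is needed; the Monte-Carlo
  round-trip test is kept anyway). This is a modeling choice consistent
  with the medians-and-IQRs reporting style, not an inference from
  data.
- **Ground truth and conservation.** The TG:VLDL-C ratio ramps linearly
  from 5 at TG = 100 mg/dL to 9 at TG = 400 mg/dL, clamped — the
  simplest shape consistent with a ratio "between 5 and 9" rising with
  TG; the shape is configurable. True VLDL-C = TG/r (in mg/dL,
  converted), and TC is *composed* as LDL + HDL + VLDL-C, so pre-noise
  cholesterol conservation holds exactly, record by record. Measurement
  noise, when on, is multiplicative log-normal with mean 1 and the
  configured CV; the default is 0 because the oracle tests reason about
  the noiseless mechanism.
- **Independence.** TG and HDL are drawn independently within sex; no
  correlation structure is claimed by the sources, so none is imposed.
- **What a green test establishes.** The simulation reproduces the
  *mechanism* — FF's TG-dependent divergence from MH/Sampson, the sign
  change of the stratified percentage difference, upward
  reclassification out of the lowest category, MH sitting above
  Sampson-NIH at high TG — and the machinery around it. It does not
  reproduce, and the acceptance criteria deliberately do not target,
  the source cohort's exact headline numbers (its kappas, rho, or Table
  medians), which depend on ~19k proprietary records: TC here is
  emergent (≈4.6 mmol/L median rather than 4.94) because it is composed
  from the other analytes, and real data carry correlation and assay
  structure the generator does not model. That the synthetic cohort
  lands close anyway (FF–MH kappa ≈ 0.70 "substantial", FF–Sampson
  ≈ 0.81 "almost perfect", MH–Sampson above 4.51 mmol/L ≈ 0.35 "fair")
  is an emergent check on the mechanism, not a fit.

## Pipeline rules

Filters apply in documented order with each record attributed to its
first failing rule, so the audit decomposes attrition exactly:
(1) age 18–75 inclusive; (2) earliest visit per patient (same-date
ties: first in stable input order, a choice the sources leave open);
(3) TG > 9.04 mmol/L excluded. `n_in = n_out + Σ removals` is asserted
on every run. The category cross-tab uses the closed TG window
[1.69, 4.51] mmol/L; Bland–Altman of MH vs Sampson-NIH uses the
half-open (4.51, 9.04]. Because the published description of the
mean-vs-difference correlation at high TG is ambiguous, the report
computes both `rho(MH, Sampson)` and `rho(mean, difference)` and labels
them distinctly. Report artifacts are deterministic (no timestamps):
identical input reproduces identical bytes.

## Known limitations

- The packaged MH table is an unverified transcription (above) and the
  2021 extended stratification is not included as a distinct object.
- No dysbetalipoproteinaemia, chylomicronaemia/non-fasting, or
  assay-interference modeling; no direct-LDL comparison; no
  Deming/Passing–Bablok regression — out of scope by design.
- The generator's independence and ramp-shape assumptions are declared,
  not fitted; conclusions drawn from it are about the machinery and the
  mechanism, not about any population.
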