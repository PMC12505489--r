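# ldlconcord

Clinical laboratories rarely measure LDL cholesterol directly: they
calculate it from total cholesterol (TC), HDL cholesterol and
triglycerides (TG). Three equations dominate practice, and they disagree
exactly where the disagreement matters — in hypertriglyceridaemic
patients near the treatment thresholds that drive statin decisions.
`ldlconcord` implements the three equations and the full concordance
analysis a laboratory needs to decide whether (and how) to switch, plus a
synthetic lipid-cohort generator with known ground truth so the whole
pipeline is testable without patient data.

For: clinical chemists, laboratory informaticians and biostatisticians
auditing calculated-LDL reporting.

## The equations

All concentrations in mmol/L (mg/dL supported throughout; cholesterol
converts at 38.67 and TG at 88.57 mg/dL per mmol/L):

- **Friedewald (FF)**, valid for TG < 4.52:
  `LDL = TC − HDL − TG/2.2`
  (assumes a fixed TG:VLDL-C mass ratio; the ratio actually varies
  roughly between 5 and 9, rising with TG).
- **Martin-Hopkins (MH)**, computed in mg/dL:
  `LDL = TC − HDL − TG/f(TG, nonHDL)`
  where the adjustable factor `f` is looked up from a stratification of
  TG by non-HDL cholesterol (`nonHDL = TC − HDL`). Original validity
  TG ≤ 4.51; the 2021 extension reaches TG ≤ 9.04.
- **Sampson-NIH**, valid for TG ≤ 9.04:
  `LDL = TC/0.948 − HDL/0.971 − (TG/3.74 + TG·nonHDL/24.16 − TG²/79.36) − 0.244`.

The concordance machinery: guideline treatment categories
(<1.81, 1.81–2.56, 2.57–3.34, 3.35–4.11, 4.12–4.89, ≥4.90 mmol/L), nine
TG strata, percentage-difference summaries, category cross-tabulations
with unweighted Cohen's kappa (Landis–Koch labels), Wilcoxon signed-rank,
Spearman rank correlation and Bland–Altman 95% limits of agreement
(bias ± 1.96·sd of paired differences).

> **Note.** The packaged 180-cell Martin-Hopkins factor table is a
> transcription that has not been re-verified against the original
> supplement; verify before any clinical use, or supply your own table
> (`read_mh_table()` — every analysis function takes a pluggable table).

## Worked example

```r
library(ldlconcord)

# one hypertriglyceridaemic panel, all three equations
compute_all(lipid_panel(tc = 5.6, hdl = 1.1, tg = 2.4), mh_table_default())
#>         ff ff_flag       mh mh_flag sampson sampson_flag non_hdl
#> 1 3.409091      OK 3.583838      OK 3.51417           OK     4.5

# a seeded synthetic cohort through the full study pipeline
rec  <- generate_cohort(cohort_config(n = 20000), seed = 42)
filt <- apply_study_filters(rec)
rep  <- run_study_analysis(filt$records, study_config(), audit = filt$audit)
rep
#> <study_report> n = 20000 records
#>   pairs: ff_vs_mh, ff_vs_sampson, mh_vs_sampson
#>   kappa ff_vs_mh: 0.697 (substantial)
#>   kappa ff_vs_sampson: 0.815 (almost perfect)
#>   kappa mh_vs_sampson_high_tg: 0.351 (fair)

rep$stratified$ff_vs_mh
#>     stratum    n median   iqr         p
#> 1     <0.57 2843 -3.265  1.37  0.00e+00
#> 2 0.57-1.12 9842 -1.572  1.18  0.00e+00
#> 3 1.13-1.68 4828  0.659  2.28 5.04e-171
#> 4 1.69-2.25 1617  4.164  5.11 7.33e-261
#> 5 2.26-2.81  556  8.253  8.18  9.10e-93
#> 6 2.82-3.38  192 14.365 11.55  2.94e-33
#> 7 3.39-3.94   67 21.817 16.28  1.12e-12
#> 8 3.95-4.51   34 23.288 22.89  3.65e-07
#> 9 4.52-9.04    0     NA    NA        NA
```

Reading the table: the `median` column is the median percentage
difference of MH relative to FF, `100·(MH − FF)/FF`, per TG stratum. At
low TG the adjustable factor sits below Friedewald's fixed ratio, so MH
reads a few percent *lower*; as TG rises the factor climbs past it and
FF increasingly *under*-estimates — the gradient from −3.3% to +23% is
the clinical problem: FF-classified patients near the lowest treatment
threshold get moved up a category by the newer equations
(`rep$reclassification_pct$ff_vs_mh` → 67.2% of FF `<1.81`
classifications in the TG 1.69–4.51 window here). Above TG 4.51, where
FF is silent, the two newer equations still disagree
(`rep$bland_altman`: MH biased +0.53 mmol/L over Sampson-NIH in this
cohort) — they are not interchangeable.

`write_report(rep, "out/")` emits the deterministic CSV/JSON artifacts
(stratified tables, cross-tab counts and row percentages, kappa,
Bland–Altman series, filter audit).

## Command line

```sh
ldlconcord simulate --n 20000 --seed 42 --out cohort.csv
ldlconcord compute  cohort.csv --out estimates.csv
ldlconcord analyze  cohort.csv --out report/
ldlconcord report   cohort.csv --out report/      # re-render with plots
```

Flags: `--config` (cohort JSON), `--seed`, `--units`, `--mh-table`,
`--extended-mh` / `--original-mh`, `--out`, `--plots`.

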