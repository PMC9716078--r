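# pvsignal

Pharmacovigilance signal detection and death-risk modelling for
spontaneous adverse-event reports, built around the question of whether
SGLT-2 inhibitors (canagliflozin, dapagliflozin, empagliflozin,
ertugliflozin) are disproportionately reported with acute pancreatitis,
and which factors predict death among those reports.

The package is aimed at drug-safety analysts working with FAERS-style
quarterly extracts ($-delimited DEMO/DRUG/REAC/OUTC/THER tables). It
covers the full analysis chain:

- **Parsing and deduplication** of quarterly tables, with the source
  system's conventions (coded age units, partial dates with carried
  precision, one record kept per case at the highest case version).
- **Cohort extraction** against a nine-term acute-pancreatitis
  preferred-term cluster, with suspect-role drug matching, per-class
  co-medication flags, and Table-style stratified summaries.
- **Disproportionality statistics** for each drug–event 2×2 table with
  cells *a, b, c, d* (N = a+b+c+d):
  - reporting odds ratio `ROR = ad/bc`, 95% interval
    `ROR·exp(±1.96·√(1/a+1/b+1/c+1/d))`;
  - information component `IC = log2(aN/((a+b)(a+c)))`, lower bound
    `IC·exp(−1.96·√V)`;
  - simplified empirical Bayes geometric mean `EBGM = aN/((a+c)(a+b))`
    (so `EBGM = 2^IC` exactly), lower bound `EBGM·exp(−1.64·√V)`.

  A pair is a **signal** when all three agree: `a ≥ 3`, `ROR025 > 1`,
  `IC025 > 0`, `EBGM05 > 1`.
- **Time to onset**: days from the earliest suspect-drug therapy start to
  the event date, summarized by median/IQR and the fraction within 180
  days.
- **Co-medication risk**: per-class adjusted odds ratios (logistic
  regression of the event flag on the class flag plus sex, age group and
  reporting year) contrasting combination therapy with monotherapy.
- **Death-risk nomogram**: 1:1 split, univariate screen (Wald p < 0.05),
  multivariate logistic fit with age forced in, a 0–100 point scale whose
  probabilities reproduce the model exactly, and validation by ROC/AUC,
  bootstrap calibration (mean absolute error over risk deciles), and
  decision-curve analysis (`NB(p_t) = TP/N − FP/N·p_t/(1−p_t)`).
- **A synthetic report generator** with known ground truth — injected
  class-level odds ratio, demographic marginals, a lognormal onset law
  (median 54 days, 83% within 180 days), co-medication odds multipliers,
  and a true logistic death model — so every stage is testable without
  access to the full regulatory database.

## Worked example

```r
library(pvsignal)

sim <- simulate_reports(sim_config(n_reports = 50000, target_prevalence = 0.05,
                                   injected_ror = 5.03, seed = 17))
reports <- deduplicate(sim$reports)
screen_all(reports)
```

```
           drug   a  ror ror025 ror975   ic ic025 ebgm ebgm05 is_signal
1       SGLT-2i 116 5.09   4.13   6.26 2.04  1.66 4.11   3.46      TRUE
2 canagliflozin  50 4.74   3.52   6.38 2.09  1.55 4.25   3.32      TRUE
3 empagliflozin  47 4.76   3.51   6.46 2.10  1.55 4.28   3.32      TRUE
4 dapagliflozin  19 3.74   2.35   5.97 1.83  1.14 3.55   2.40      TRUE
5 ertugliflozin   0   NA     NA     NA   NA    NA   NA     NA     FALSE
```

The class row recovers the injected odds ratio of 5.03 within Monte-Carlo
error (a = 116 co-reports), and every member with at least three cases
meets the triple criterion; ertugliflozin drew no cases at this size and
is reported as an explicit no-case row rather than a number.

```r
cohort <- extract_cohort(reports, require_demographics = TRUE)
summarize_tto(cohort$onset_days[cohort$ap])
#> <tto_summary> n=116 | median 68.0 d (IQR 27.0-126.0) | 80.2% within 180 d
```

The onset summary reflects the generator's lognormal law (median 54 days,
83% within six months) at this sample size. An end-to-end run — simulate,
extract, screen, onset summary, co-medication odds ratios, death model —
is one call:

```r
run_pipeline(pipeline_config(out_dir = "analysis", seed = 17,
                             sim = list(n_reports = 20000L,
                                        target_prevalence = 0.5,
                                        injected_ror = 8)))
```

which writes every intermediate (cohort, signals, onset summary,
co-medication table, death-model coefficients, nomogram, calibration and
decision curves) plus a `manifest.json` with the attrition chain. A thin
command-line wrapper for each stage is in `inst/cli/pvsignal.R`.

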