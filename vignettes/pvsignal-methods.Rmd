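---
title: "Methods: disproportionality screening and death-risk modelling for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and death-risk modelling for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect unsolicited reports
of suspected adverse drug reactions. They have no denominator — nobody
knows how many patients took a drug without incident — so the workhorse
of signal detection is *disproportionality*: does a drug–event pair
appear more often than the rest of the database would predict? This
package implements that analysis for the SGLT-2 inhibitor / acute
pancreatitis question, together with the downstream questions a safety
assessor asks once a signal is found: how soon after starting therapy
does the event occur, do co-medications modify the risk, and what
predicts death among the reported cases.

Because the full regulatory database is too large (and too encumbered)
to ship, the package pairs every analysis stage with a synthetic
generator whose ground truth is known. The generator is first-class,
tested code: parameter-recovery tests run the real analysis code on
simulated data and check that it returns the quantities that were
injected.

## Report model and parsing conventions

A report set is held relationally, mirroring the quarterly extract: five
linked tables (demographics, drugs, reactions, outcomes, therapy dates)
keyed by `primary_id`. Conventions worth stating:

- **Age units.** The source codes ages in decades (`DEC`, ×10), years,
  months (÷12), weeks (÷52.18) or days (÷365.25). Results outside
  [0, 120] years become missing rather than propagate.
- **Partial dates.** `YYYYMMDD`, `YYYYMM` and `YYYY` are all legal; the
  parsed date is anchored to the first day of the coarser period and a
  precision flag (`day`/`month`/`year`) is carried. Day-resolved
  arithmetic (time to onset) refuses anything coarser than `day`.
- **Deduplication.** One record per `case_id`: highest `case_version`
  wins, ties broken by latest report date, then largest `primary_id`.
  The operation is idempotent.
- **Drug matching.** The drug-name field is free text, so class
  membership is case-insensitive substring matching against ingredient
  and major brand names. Event matching is the opposite: the nine
  acute-pancreatitis preferred terms are matched exactly
  (case/whitespace-insensitive), with no hierarchy traversal.
- **Suspect roles.** Cohort membership and the 2×2 exposure cell require
  the drug in a suspect role (`PS`/`SS`). Concomitant-only mentions
  dilute signal; a `roles` argument relaxes this when needed.
- **Heart failure.** Concomitant disease is not a first-class field in
  the extract; the heart-failure flag is read from drug indication
  strings, which is where prescribing context lives in this format.

## Disproportionality statistics

For a 2×2 table (a = target drug & target event, b = drug only, c =
event only, d = neither; N = a+b+c+d), three statistics are computed:

- `ROR = (ad)/(bc)` with the lognormal Wald interval
  `ROR·exp(±1.96·√V)`, `V = 1/a+1/b+1/c+1/d`;
- `IC = log2(aN/((a+b)(a+c)))` with lower bound `IC·exp(−1.96·√V)`;
- `EBGM = aN/((a+c)(a+b))` with one-sided lower bound
  `EBGM·exp(−1.64·√V)`.

In this simplified (relative-reporting-ratio) form `EBGM = 2^IC` holds
as an algebraic identity, and the test suite asserts it to 1e-9 on every
small table. No gamma-Poisson shrinkage is applied; a full empirical
Bayes fit is out of scope by design.

Numerical choices:

- The multiplicative IC bound is undefined in spirit for `IC ≤ 0` (the
  log of a non-positive number); there the additive bound
  `IC − 1.96·√V` is used instead, keeping the statistic total. The
  standard credible-interval approximation
  `IC − 3.3·a^(−1/2) − 2·a^(−3/2)` is available behind
  `ic_with_bound(..., method = "credible")`.
- Zero cells in b, c or d trigger the Haldane–Anscombe correction: 0.5
  added to **all four** cells for both point estimates and variance
  terms, so estimates stay finite and symmetric. `a = 0` is different in
  kind — there is no case to describe — and returns an explicit
  undefined result (`defined = FALSE`, never a signal) rather than an
  exception, so class-wide screens stay total.
- A pair is a signal only when all three criteria agree: `a ≥ 3`,
  `ROR025 > 1`, `IC025 > 0`, `EBGM05 > 1`. The triple intersection is
  deliberately conservative; the null-simulation acceptance check
  observes a false-signal rate well under 10%.

## Time to onset

The interval is event date minus the *earliest* day-precision therapy
start of a suspect-role target drug. Negative intervals (event before
therapy) are treated as missing and counted as anomalies rather than
clamped. Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7) — the most common statistical-software
default; the "within six months" fraction uses 180 days at day
resolution.

## Co-medication odds ratios

Within the target-drug cohort, each co-medication class gets its own
logistic model of the event flag on the class flag plus adjusters
(default: sex, age group, reporting year — the covariates that vary
across the cohort strata). Fitting one model per class mirrors
forest-plot practice and avoids collinearity among correlated
co-medication flags. The logistic fitter is `stats::glm` (IRLS,
tolerance 1e-8, max 100 iterations) wrapped to return a tidy coefficient
table with Wald intervals; complete separation is flagged
(`separation = TRUE`, `converged = FALSE`) instead of raised, since a
screen over many classes must not die on one degenerate stratum.

## Death-risk model and nomogram

The modelling path mirrors standard clinical-prediction practice:

1. simple random 1:1 split (seeded; a stratified option exists but is
   off by default, matching a plain randomization);
2. univariate screen with a joint Wald test per candidate (all levels of
   a categorical predictor at once), entry threshold p < 0.05;
3. multivariate logistic fit of the retained factors with **age always
   forced in** — age is clinically non-ignorable for mortality even when
   a small training half leaves it non-significant; a switch disables
   this;
4. a point-scale nomogram: each term's contribution is rescaled so the
   largest |coefficient × observed range| spans 0–100 points and every
   reference level maps to 0 points. The total-points → probability map
   goes through the reconstructed linear predictor and the logistic
   link, so nomogram probabilities equal model probabilities to
   floating-point accuracy (asserted to 1e-9).

The SGLT-2i type enters as a categorical predictor with canagliflozin
(the largest stratum) as reference. In the pipeline, type levels with
fewer than 10 cohort reports are merged into the largest level before
the split: a level that thin cannot support its own dummy coefficient in
half the data and otherwise produces unseen-level failures at validation
time.

Validation:

- **AUC** is the Mann–Whitney statistic (ties count ½), identical to the
  trapezoidal area and cross-checked in the tests against an O(n²)
  pairwise oracle.
- **Calibration** refits the model on bootstrap resamples, scores the
  *original* data, bins by deciles of the original predictions (empty
  bins merge via unique quantile breaks), and reports the mean absolute
  predicted-minus-observed difference averaged over resamples. Decile
  bins, not a smoother, so the number is exactly reproducible.
- **Decision curves** report `NB(p_t) = TP/N − FP/N·p_t/(1−p_t)` with
  treat-all and treat-none references on a 0.001–0.5 grid (thresholds
  ≥ 1 are excluded; at `p_t = 0` the net benefit equals prevalence
  exactly).

## The synthetic generator

`sim_config()` fixes the study conditions; its defaults are the
documented cohort characteristics, chosen once:

- **Demographics.** Sex, age group, reporting year, reporter, country
  and per-drug share are drawn independently from the cohort's marginal
  proportions (only marginals are published, so no dependence structure
  is imposed). Age is drawn from a normal law (mean 56.2, sd 12.1 years)
  truncated within the sampled age-group bounds, reproducing both the
  group marginals and the cohort mean age. Body weight: normal
  (95.8, 24.4) kg with 55.9% missingness, the observed share.
- **Event assignment.** A report's suspect drug is a target-class member
  with probability 0.01, and a non-target report carries the event with
  probability 0.01 — both free parameters (the source publishes neither
  the class denominator nor the database size); these values make the
  target class and the event each rare at realistic reporting-database
  orders. The target arm follows
  `odds(event | target) = injected_ror × odds(event | other)`, with
  per-co-medication odds multipliers (defaults: the published adjusted
  odds ratios — 1.39 DPP-4i, 1.97 GLP-1RA, 1.29 metformin, 1.21 insulin,
  2.55 glinide, 1.34 ACEI, 1.32 PPI, statin 1.0). Because odds ratios
  are non-collapsible, the target-arm baseline is calibrated by
  enumerating all 2^8 co-medication patterns and solving for the odds
  scale that makes the *marginal* class-level odds ratio equal
  `injected_ror` exactly; without this the marginal ratio would sit a
  few percent low.
- **Onset times.** Lognormal with median 54 days. The published
  summaries (median 54, IQR 14–131, ~83% within six months) cannot all
  be matched by one lognormal — the printed IQR is asymmetric on the log
  scale — so sigma is calibrated to the median and the six-month
  fraction: `sdlog = ln(180/54)/Φ⁻¹(0.83) ≈ 1.262`, giving an implied
  IQR of roughly 23–127 days. The tail fraction was preferred because it
  is the summary the downstream analysis consumes.
- **Death.** A true logistic model on target reports: intercept −5.0,
  0.02 per year of age, 0.9 for statin use, 0.6 for heart failure, and
  type contrasts 0.7/0.3/1.5 (dapagliflozin/empagliflozin/ertugliflozin
  vs canagliflozin). At the default covariate mix this yields a death
  rate near 4%, matching the observed 4.2% share. Non-target reports
  die at a constant 3% background rate.
- **Missingness** is injectable per field (sex, age, therapy start;
  default 0) to exercise the exclusion rules; duplicate case versions
  are injectable via `dup_fraction` to exercise deduplication.

What the generator does **not** emulate: correlated demographics,
multi-ingredient products, indication-driven channeling
(co-medications are independent of demographics), secular reporting
trends within a year, and duplicate reports that differ in content
rather than version. Passing recovery tests therefore show the
*estimators* are correct under clean conditions, not that real FAERS
data meet those conditions.

## Problem sizes and reproducibility

All randomness flows from explicit seeds (one root seed per pipeline
run, split per stage). The test suite and the acceptance script use
problem sizes chosen to keep each check's Monte-Carlo error well inside
its tolerance: 500,000-report datasets for class-level recovery (the
binomial error of a single realized table is about 7% on the log odds
ratio, so recovery is judged on the geometric mean of three replicates);
100 seeds of 20,000 reports for the null false-signal rate; 50,000-row
cohorts for death-model coefficient recovery (±15% bands); 5,000 draws
for onset-law calibration; bootstrap calibration at 200 resamples, which
is enough for a stable MAE at the 0.01 scale.

## Known limitations

- The simplified EBGM is a relative reporting ratio; it will not shrink
  small-count cells the way a full gamma-Poisson fit would, and small-a
  rows should be read with the `a ≥ 3` criterion firmly in mind.
- The multiplicative IC bound inherits the Wald variance; for very small
  a the credible-interval option is the safer read.
- Wald intervals (not profile likelihood) throughout the logistic layer;
  at the event counts involved the difference is immaterial, but
  separation-flagged fits should not be interpreted numerically.
- The cohort builder takes the first matched SGLT-2i as the report's
  type when several are listed; such reports are dropped on the
  death-model path anyway.
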