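---
title: "Forecasting drug-shortage impact: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting drug-shortage impact: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortcast)
```

## The problem

When a drug product (identified in Canada by its DIN) becomes unavailable,
pharmacists substitute another product from the same interchangeable group
(IG) without physician involvement. Only when a whole IG runs dry must they
escalate to neighbouring therapeutic classes (TCs), which requires physician
authorization and carries clinical risk. Pharmacies see only demand-side
data — their own dispensing records — plus the public shortage registry in
which manufacturers must report shortages per DIN and pack size. `shortcast`
implements a forecasting pipeline over exactly those inputs: it cleans raw
shortage reports, converts them into a monthly *shortage impact score* per
IG, engineers lagged demand and hierarchy features, and fits one
gradient-boosted tree regressor per IG to predict next month's score.

## The shortage impact score

For IG $w$ with component DINs $d$, the score in month $t$ is

$$ S_w(t) \;=\; \sum_{d \in w} \omega_d(t)\, u_d(t), $$

where

* $u_d(t)$ is the fraction of $d$'s pack listings unavailable in month $t$.
  All listings of a DIN are treated as equally important (order-share data
  per pack do not exist on the demand side), so a DIN with one of its two
  listings shorted all month has $u_d = 0.5$. Within a month a listing
  contributes the fraction of days it spends inside a shortage interval,
  with overlapping intervals counted once.
* $\omega_d(t)$ is $d$'s share of the IG's *historical* days of supply
  (DOS): cumulative DOS from the start of the series through month $t-1$,
  divided by the IG total over the same window. Weights therefore sum to 1
  and never use information from month $t$ itself.

$S_w \in [0,1]$: 0 when everything is available, 1 when nothing in the IG
is. A DIN holding 40% of historical DOS with half its packs shorted
contributes $0.5 \times 0.4 = 0.2$.

Three choices here were genuinely open:

* **"Past" usage window.** Cumulative-from-start is reproducible and
  leak-free; a trailing window would let weights drift faster but adds a
  tuning constant. Cumulative is the default; nothing in the pipeline
  depends on the choice structurally.
* **Within-month aggregation.** The score is defined at daily resolution
  but reported monthly; we average the daily indicator over the month's
  days. Shortages aligned to month boundaries (the synthetic generator's
  default) make every obvious convention agree.
* **Weight basis.** Dispensing frequency could be measured by patients or
  by DOS; the DOS-based definition is the one with a worked magnitude
  attached, so it is the implementation, with patient-based shares still
  available in the feature layer.

## Cleaning raw shortage reports

Registry exports are messy in specific, recurring ways, and the cleaning
stage (`build_intervals()`) encodes one rule per defect:

* Only `actual` shortages matter; anticipated and avoided reports are
  dropped. Reports whose (imputed) start predates March 2017 — the start of
  mandatory reporting — are excluded.
* Missing dates are imputed by cascade: start = actual start, else
  anticipated start, else report-entry date; end = actual end, else
  last-updated date. Records whose end is unrecoverable or whose start
  exceeds their end are *rejected and counted*, never silently dropped.
* Pack sizes arrive as free text ("100 Bottle", "100 BTL", "10x10
  Blister"). We extract all digit runs, match them against the DIN's
  catalog listings by size, then by the product of all numbers (catching
  multiplicative renderings), and fall back to *all* listings of the DIN
  when nothing matches — the conservative reading of an ambiguous report.
  A numeric size matches every listing with that size; manufacturers are
  not distinguished within a size.
* Shortages that are still open at the data horizon have their imputed end
  clamped to the caller-supplied last data day (`clamp_end`), an explicit
  interpretation the registry leaves open.

## Features

Each IG's design matrix has one row per month. The target is the
contemporaneous impact score; every predictor enters at lags 1–4 only, so a
forecast for month $t$ uses information through $t-1$ — a 30-day warning
horizon. Families:

* per-DIN demand: average DOS per patient, total DOS, quantity dispensed,
  prescription count (so the column set varies with IG size);
* IG aggregates: DOS, quantity, prescriptions, DOS per patient;
* `chg_dist_pat` / `chg_dist_dos`: the maximum absolute month-to-month
  change in DIN shares (in percent), a substitution-churn signal;
* `gini_pat` / `gini_dos`: preference concentration. We use the mean
  absolute pairwise difference of shares, rescaled by $n/(n-1)$ so that
  full concentration on one DIN yields exactly 1 at any group size and a
  uniform allocation yields 0;
* `shortage_tc`–`shortage_tc3`: shortage pressure among *other* IGs whose
  TC code shares the target's prefix at levels 0–3, aggregated as a
  DOS-weighted mean (weights = neighbours' cumulative DOS through the prior
  month). The weighting mirrors the demand-weighting used in the score
  itself; unweighted mean or max would also be defensible but would ignore
  that a shortage in a high-volume neighbour matters more.
* An optional month-over-month IG-DOS difference (`dos_change`) exists
  behind a flag, default off: it is a seasonality proxy that the variable
  roster of the reference analysis does not list separately, and lagged DOS
  levels already span it.

Rows whose lag window reaches before the data start are dropped (the
share-change features additionally need one prior month, so the first
usable row sits at month `lags + 2`).

## Models and validation

One xgboost regressor per IG (trees = 300, depth = 4, learning rate = 0.1,
subsample = 0.9; single-threaded, seeded, hence bit-reproducible).
Hyperparameters were fixed a priori at common defaults for small tabular
problems; no tuning loop runs by default. Degenerate targets (an IG that
never experiences a shortage) fit cleanly to the constant. Predictions are
clipped to $[0,1]$.

Validation uses expanding-window blocked resampling: split $k$ trains on
the first $12 + k - 1$ months and tests on the next month, so a 48-month
span yields 36 resamples and every test block strictly follows its training
window. The final evaluation refits each IG once on all pre-holdout months
and predicts the last four months one step ahead from *observed* lagged
features: reported shortages are public monthly facts, so at deployment
time the lag-1 regressors for month $t$ are known. (A recursive mode would
compound forecast errors across the holdout and answers a different
question; the one-step-ahead design matches the stated horizon.)

Feature importance is permutation-based: the mean MAE increase over seeded
shuffles of each column, floored at zero, normalized to percentage shares,
and aggregated by family (summing over lags and DINs) and by family × lag.
IGs are weighted equally when averaging across groups.

## Evaluation battery

`evaluate_forecasts()` reproduces the full battery: overall/per-IG MAE;
binning of scores into None (= 0), Low ((0, 0.33]), Medium ((0.33, 0.67]),
High ((0.67, 1]); the 4×4 confusion matrix with accuracy, an exact
Clopper–Pearson 95% interval (a normal interval is selectable) and
unweighted Cohen's kappa; one-vs-rest precision/recall/specificity with
zero-denominator cases flagged `NaN` rather than imputed; per-bin mean
actual, mean forecast and MAE; and impactful-shortage detection — an
IG-month with actual score ≥ 0.5 counts as detected when the forecast also
reaches 0.5.

## The synthetic generator

Real pharmacy dispensing data are proprietary, so `simulate_shortage_data()`
emulates the statistical structure the pipeline assumes, and every
downstream stage is tested against it:

* a drug hierarchy in which several IGs share TC prefixes at each level
  (so neighbour features are exercised);
* per-IG DIN shares drawn from a Dirichlet with configurable concentration
  and evolving as a slow multiplicative random walk — stable preference
  with drift;
* a latent shortage process per DIN/pack-size with monthly hazard 0.02 and
  durations $1 + \mathrm{Geom}(0.4)$ months, optionally propagating to a
  TC sibling the next month;
* demand response with a one-month lag: patient share multiplied by
  $1 - s \cdot u$ (substitution strength $s = 0.6$) and renormalized, DOS
  per patient reduced by $0.3 \cdot \bar u$ during large shortages, plus a
  12-month seasonal cycle;
* raw reports rendered through free-text pack-size dialects with
  configurable rates of blanked and inverted dates, and a latent-truth
  ledger emitted purely so tests can compare cleaned intervals against
  ground truth.

Defaults describe a 20-IG study over January 2017–April 2021 with ~200
patients per IG-month; demand-side magnitudes are order-of-magnitude
choices (no public calibration target exists) and are config-exposed, not
asserted. The generator reproduces the *mechanisms* the analysis relies on
— persistence, substitution shifts, preference concentration, hierarchy
spillover — but not the volume distribution, reporting cadence or
pharmacy-mix of real data; green tests demonstrate correctness of the
pipeline's logic, not real-world forecast skill. Shortages align to month
boundaries by default (a `day_level` flag exercises the day-fraction
convention); report-level status noise is governed by `status_probs`, and
the round-trip property (cleaned intervals ≡ latent ledger) holds exactly
when defects are off and all dialects are parseable.

## Numerical conventions and degenerate inputs

* Gini of a single-DIN group is 0; zero-total months fall back to uniform
  shares; `avgdos_pat` with zero patients is 0, keeping tree inputs dense.
* Weights, scores and forecasts are clipped to their unit ranges only
  against floating-point rounding; clipping never masks a modelling error.
* All month arithmetic is calendar-exact (`"YYYY-MM"` keys, whole-day date
  comparisons); February lengths and leap years come from `Date`
  arithmetic, not 30-day approximations.
* Test problem sizes: the full-scale check runs 100 IGs over 52 months
  (400 holdout forecasts); property suites use hundreds of small random
  instances against brute-force daily/pairwise oracles at tolerance 1e-12.

## Known limitations

* Scores aggregate all pharmacies jointly; pharmacy-level stratification is
  out of scope.
* Classical time-series baselines (ARIMA/ETS) are not implemented; the
  package commits to the boosted-tree engine.
* The synthetic generator's magnitudes are plausible rather than
  calibrated; headline accuracy numbers on synthetic data are not
  comparable to results on real dispensing records.
* Partial availability (residual pharmacy stock during a reported
  shortage) is not modelled; a reported shortage makes a listing fully
  unavailable for scoring purposes.
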