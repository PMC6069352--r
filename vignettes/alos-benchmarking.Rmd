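---
title: "Benchmarking aggregated length of stay from admission records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking aggregated length of stay from admission records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Postoperative length of hospital stay (LOS) is the standard surrogate for
recovery and resource use after digestive cancer surgery, but the index
stay alone understates true bed use wherever care is centralised: patients
operated at a tertiary centre are frequently handed over to a local
hospital the day they leave the operating institution, and a substantial
fraction are readmitted within a month. `alosbench` implements the
*aggregated length of stay* (a-LOS): the number of nights a patient spends
in **any** hospital during the 30 nights following the index operation,
decomposed into index stay, transfer stays and readmission stays. From
patient-level admission records it extracts a resection cohort over eight
benchmark groups — oesophageal, pancreatoduodenectomy (Whipple), rectal,
gastric, distal pancreatic, colonic, major liver and minor liver
resections — classifies surgical access (open, laparoscopic, converted),
links each case's episode of care, and tabulates, per group and access:
n, median index LOS, transfer rate and median transfer stay, readmission
rate and median readmission stay, and median (i.q.r.) a-LOS.

Because national patient-register extracts cannot be redistributed, the
package ships a synthetic registry generator with known ground truth,
calibrated to published national benchmark values, so that every pipeline
stage is testable end to end.

## Definitions and conventions

All stays are counted in *nights* (midnight census): a stay contributes
the nights of the dates `admission .. discharge - 1`, so same-day
admission and discharge is 0 nights. Dates are ISO calendar dates; there
are no times anywhere in the model.

* **Index LOS** — nights from the surgery date to the first discharge or
  transfer from the operating institution. Back-to-back rows at the same
  hospital (a new admission on or before the previous discharge date) are
  merged first, so within-institution handovers extend the index stay.
  Index LOS is reported untruncated.
* **Transfer stay** — an admission to a *different* hospital on the same
  calendar date as discharge from the index (or previous transfer)
  hospital. Chains are followed transitively, and every link is classed as
  a transfer.
* **Readmission** — an admission to any hospital within 30 days of surgery
  (closed window: day 30 counts, day 31 does not), separated by at least
  one full night out of hospital from every index/transfer interval
  already begun by then. A stay overlapping such an interval never
  qualifies.
* **a-LOS** — the size of the union of occupied nights, over all of the
  patient's stays, intersected with nights 1–30 after surgery. Using the
  occupancy union means overlapping records are never double counted; with
  non-overlapping stays a-LOS equals clipped index + transfer +
  readmission nights. By construction `0 <= a-LOS <= 30` and
  `min(index LOS, 30) <= a-LOS`.

"Within 30 days" is everywhere a closed window of calendar days
(difference of at most 30). Whether a register analysis counts day 30 is
an interpretation choice; we apply the closed reading uniformly (cohort
diagnosis window, reoperation window, readmission window) and flag it here
as the sensitivity point.

## Cohort extraction rules

A *candidate resection* is a distinct (patient, date, organ group) with a
mapped resection procedure code. Candidates pass through, in order:

1. **Colonic malignancy filter** — colonic resections are retained only
   with a colonic malignancy diagnosis coded within ±30 days of surgery
   (resections of the other organs are assumed performed for malignant or
   premalignant disease and are not filtered).
2. **Same-date ranking** — when two organs are resected on one date only
   the higher-ranked is kept (ranking: oesophageal, pancreatoduodenal,
   rectal, gastric, distal pancreatic, colonic, liver); the rest are
   excluded as secondary resections.
3. **Reoperation rule** — a candidate 1–30 days after an already *kept*
   case of the same patient is excluded as a reoperation. Excluded cases
   do not anchor further exclusions (exclusion chains are not modelled;
   kept-case anchoring is the minimal reading).

Access is classified from the surgery-date codes of the candidate's own
organ group: open unless a designated laparoscopic code is present, and
*converted* when both a laparoscopic and an open code appear. Liver
resections split into major (three or more consecutive segments — the
Brisbane 2000 criterion, carried as a per-code flag in the code map) and
minor; when codes of both extents co-occur on one date the larger
resection wins. The extraction report (candidates, colonic exclusions,
reoperation/secondary exclusions, final cohort) balances by construction
and is checked at run time.

The bundled code map uses NCSP-style stems and is explicitly
*illustrative*: register extractions use the full NOMESCO procedure
classification, which is not published as a reusable list. Both the
procedure map and the colonic-malignancy diagnosis prefixes are
configurable (`load_codemap()`).

## The synthetic registry

The generator emulates a 5-year national cohort. For every benchmark group
and access class it draws case counts (largest-remainder apportionment of
the published access mix), index LOS, transfer events and stay lengths,
and readmission events, delays and stay lengths, then emits admission
rows: an index admission carrying the resection code(s) on the surgery
date (converted cases carry one laparoscopic and one open code), an
optional same-date transfer admission at another of the group's hospitals
(with a small configurable chance, 0.05 by default, of a second same-date
handover, exercising chain handling), and an optional readmission
admission. Hospital counts per group reflect centralisation (4 hospitals
for oesophageal surgery up to 32 for colonic). Every generated case has a
ground-truth row with its true labels and night counts, so label recovery
can be asserted exactly.

### Stay-length model

Published tables report stay lengths as median (i.q.r.) only, so a
generative family must be chosen; this is a modelling decision, not a
property of any register. We use a **discretised log-normal** — the
standard right-skewed choice for LOS — with `sigma` solved from the
quartile ratio and `mu` fitted by least squares over the three reported
log-quantiles (three constraints, two parameters). This keeps the sampled
median within one night of the target even for heavily skewed cells
(e.g. laparoscopic major liver a-LOS 5 with i.q.r. 3–16), at the cost of a
modest shift of the sampled quartiles towards the median; matching the
quartiles exactly instead was rejected because it misses published medians
by up to 2.5 nights on such cells.

Index-LOS quartiles are not published at all. We anchor them to the
published a-LOS shape of the same group × access cell: index q1/q3 are the
index median scaled by the cell's a-LOS q1/median and q3/median ratios.
Transfer and readmission stays, with only medians published, use a generic
right-skew rule (q1 = 0.6 × median, q3 = 1.8 × median) and are clamped to
at least one night, since registers record only transfers and readmissions
involving an overnight stay.

### Timing and noise channels

Admission precedes surgery by 0–1 days (30% chance of next-day surgery).
Readmission delays are drawn uniformly on `[last episode discharge + 2,
30]` days after surgery, anchored on the last discharge of the whole
index + transfer chain so the one-night separation always holds for
generated readmissions. A consequence worth knowing: groups with long
index/transfer stays cannot always fit a readmission into the window, so
their *realised* readmission rate falls below the configured probability
(about 2.5 points low for oesophageal resections, negligible for
short-stay groups). This is a feasibility property of the 30-day window,
not an extraction defect; tests therefore assert readmission-rate recovery
on groups where the window binds rarely.

Four noise channels exercise the exclusion filters: colonic cases without
a malignancy code (they carry a benign colonic diagnosis instead),
same-date secondary resections (a minor-liver code added to a non-liver
case's surgery date), reoperations (a same-site resection in its own
admission 1–30 days after an eligible case, with a fresh malignancy code
for colonic anchors so only the reoperation rule removes it), and
unrelated admissions (default rate 0, available to stress the occupancy
union). Noise counts are **deterministic** (`round(fraction * n)`), so the
extraction accounting of a given configuration is exact and repeatable —
`national_cohort_config()` reproduces the published flow-chart arithmetic
(32 397 candidates; 6 977 colonic exclusions; 1 066 reoperation/secondary
exclusions; 24 354 analysed) identically for every seed. The published
split of the 1 066 reoperation/secondary exclusions is not stated; the
configuration uses 800 reoperations + 266 secondaries so both paths are
exercised at scale.

`default_config()` generates the *analysed* cohort (all noise off, equal
group sizes, 2 000 cases per group by default): published rates and
medians are treated as target outputs of the included cohort, and leaving
reoperation noise on would re-enter those stays as readmissions of the
anchor cases and bias recovered rates upwards by ~3 points. Demographics
(age ~ normal(68.3, 12) truncated to 18–100; male with probability 0.513)
have no column in the registry format and are carried in the ground truth
only.

### What the generator does not model

Case mix and co-morbidity (not available in the emulated register either,
so no adjustment is attempted downstream), mortality censoring, seasonal
or secular trends, correlation between stay length and transfer or
readmission risk beyond the access/group stratification, ward-level moves
(folded into the index stay by definition), and cause of readmission.
Passing recovery tests therefore show that the *pipeline* is correct and
well calibrated — not that real registry data behave like the simulator.

## Numerical and reporting conventions

* Medians use the midpoint convention; quartiles use linear interpolation
  between order statistics (`quantile()` type 7). Published half-integer
  a-LOS quartiles pin down the median convention but not the quartile
  rule, so the convention is a documented, configurable choice
  (`quartile_type`).
* Percentages are rounded half-up to one decimal (so 37.575 prints as
  37.6), matching benchmark-table style; base R's round-half-even is not
  used for reporting.
* Box-whisker statistics: upper whisker `q3 + 1.5 * iqr`, lower whisker
  the smallest observation at or above `q1 - 1.5 * iqr`; means are
  reported alongside and are right-skewed because a-LOS is truncated at
  30. Converted cases are pooled into the open group for plots only; the
  benchmark table keeps them as their own rows.
* Same-date ties: two same-date admissions at different hospitals at a
  transfer handover are broken by hospital-id order; candidate aggregation
  ties (multiple admissions carrying the same organ's codes on one date)
  keep the first admission row in (record, code) order. Both are logged
  deterministic choices.
* Degenerate inputs: empty registries yield empty cohorts and zero-count
  reports rather than errors; `summarize_cohort()` requires at least one
  episode; a surgery date outside every index-hospital stay is an error
  (it indicates an inconsistent cohort/registry pair).

## Problem sizes

The package's own test-and-verification runs use: exact worked examples at
n of a few stays; property suites over 100–200 randomised stay sets;
parameter recovery at 2 000 cases per group (16 000 cases, ~25 000
admissions); and the full national-scale accounting run (31 331 primary
cases, ~40 000 admissions). The complete pipeline at national scale runs
in well under a minute on a single core; episode linkage is the dominant
stage (~0.5 ms per case).

## Known limitations

* The code map is illustrative; fidelity to any real register extraction
  requires supplying the site's own code list.
* a-LOS group medians are *emergent* in the simulator (index + transfer +
  readmission realisations), so they track but do not exactly equal the
  published a-LOS cells used to shape the index distribution; the
  calibration targets that are asserted are the directly configured
  quantities (index medians, transfer/readmission rates) plus the
  headline a-LOS cells with a ±1-night band.
* The readmission feasibility bias for long-stay groups, described above.
* No statistical comparison between groups is provided, by design: the
  benchmark is descriptive.
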