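---
title: "Auditing newborn admission records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing newborn admission records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naraudit)
```

## The problem

Neonatal units in low-resource settings admit thousands of babies a year on
paper records. Whether essential interventions — thermal care, oxygen,
timely antibiotics at the right dose — are actually delivered is hard to
monitor when the admission record itself is incomplete. Audit-and-feedback
(A&F) programmes attack this by measuring documentation quality on a
standardised newborn admission record (NAR), feeding the results back to
clinicians at regular meetings, and tracking whether the measured quantities
improve. `naraudit` implements the measurement half of that loop: a
versioned data dictionary for the NAR, completeness scoring with binomial
confidence intervals over six-month periods, variable-level missingness
stratification, and a weight-banded gentamicin dosing-correctness audit —
plus a seeded synthetic cohort generator so the whole pipeline can be
exercised and tested without access to identifiable hospital data.

## Data model

**Dictionary.** The default dictionary (`nar_dictionary()`) describes the
revised 2014 NAR: 50 variables in six domains — maternal history (6),
demographics and diagnosis (12), presenting complaints (6), cardinal signs
on examination (4), other physical examination (18) and vital signs (4).
Each variable has a value kind (`numeric`, `categorical`, `date`, `text`)
and, where the kind supports it, a validity constraint: a numeric range or
a category set. Fourteen variables were added at the 2014 form revision
(all six maternal-history items, seven examination signs, and oxygen
saturation) and carry `introduced_in = "revised2014"`; the pre-revision
form is the remaining 36 variables. `load_schema("baseline")` and
`load_schema("revised2014")` select the two versions; user dictionaries in
the same YAML layout (`read_dictionary()` / `write_dictionary()`) can
extend or re-bound the default — the shipped ranges (temperature 30–42 °C,
birth weight 0.4–6.0 kg, respiratory rate 10–120/min, …) are
plausibility limits chosen by us, since point-of-entry checking systems
rarely publish their bounds.

**Two layers per admission.** An admission table carries *register* fields
(`record_id`, `adm_date`, `dob`, `vital_status`, true `weight_kg`, form
`schema_version`, the 60%-sample `full_dataset` flag, …) that the unit
always knows, and *documentation* columns named exactly as in the
dictionary, in which an empty cell means the form was not filled in. The
two layers deliberately use different names where they overlap (e.g.
register `adm_date` vs documentation variable `admission_date`): the
register drives period binning and joins even when the form itself omitted
the admission date, and the documentation layer is what gets scored. This
mirrors how such audits actually run — the census is known; the question is
what the clinician wrote down.

**Validity checking.** `validate_record()` reproduces point-of-entry
range/validity checks: out-of-range numerics, unknown categories,
unparseable dates and date inversions each yield one finding. Absence is
*never* a finding; missingness is measured by the completeness statistics,
not flagged as invalid.

## The completeness statistic

Each variable on each admission gets a binary availability score: 1 if a
non-empty value is documented (after whitespace trimming), 0 if not, and
*not applicable* if the variable was not on that record's form version.
The per-domain, per-period statistic is pooled over slots:

$$\hat p_{d,t} = \frac{\sum_{i \in t}\sum_{v \in d} \mathbf{1}[\text{documented}_{iv}]}{\sum_{i \in t}\sum_{v \in d} \mathbf{1}[\text{applicable}_{iv}]}$$

Not-applicable slots are excluded from numerator and denominator alike, so
pre-revision records are not penalised for variables their form never
carried — the denominator counts only what *could* be documented. A
domain-period cell with no applicable slots is an explicit error in
`domain_completeness()` (never silently 0/0); `completeness_table()`
reports such cells with `n = 0` and no estimate so mixed-version cohorts
tabulate cleanly. A per-patient score (`patient_completeness()`) and a
patient-mean aggregation (`completeness_table(method = "patient_mean")`)
are also provided; pooling is the default because the audited quantity is
the documentation rate of the patient population over the period, and the
two differ only when per-record denominators differ (mixed form versions in
one bin).

**Stratification.** `stratify_variable()` classifies a variable by its
documented fraction among applicable records: `very_poor` below 25%,
`poor` from 25% to 50%, `adequate` above 50%. Both thresholds are assigned
inclusively to `poor` (a fraction of exactly 0.25 or 0.50 is `poor`), so
the three strata partition [0, 1] with no gaps; nothing above 50% is
labelled poor. We stratify on the *documented* fraction (not the missing
fraction) because the strata labels describe documentation levels.

## Interval estimation

All proportions carry Wilson score intervals by default: with
$\hat p = x/n$ and $z$ the normal quantile,

$$\frac{\hat p + \frac{z^2}{2n} \pm z\sqrt{\frac{\hat p(1-\hat p)}{n} + \frac{z^2}{4n^2}}}{1 + \frac{z^2}{n}}.$$

The Wilson interval is well behaved at 0 and 1 (its lower bound is exactly
0 at $x = 0$), and it is the method whose bounds agree with the interval
arithmetic used in routine neonatal audit reporting, where the Wald
interval visibly disagrees at proportions near 10%. The reported point
estimate is always $x/n$, never the Wilson midpoint. A Clopper–Pearson
(exact) alternative is available via `period_config(ci_method =
"clopper-pearson")` for users who need guaranteed-conservative coverage.
Percentages are displayed to one decimal in written outputs; internal
values are never rounded.

**Periods.** The default binning is calendar half-years from study start to
end (first and last bins clipped to the window), with the pre/post-A&F
phase boundary at the form-revision date. Real audit calendars are messier
— a revision mid-bin, a truncated final period — so a bin can straddle the
phase boundary (phase attaches to the date, not the bin) and
`period_config(bin_edges = ...)` accepts arbitrary explicit edges.

## The dosing audit

The default `dose_rule()` is the national neonatal gentamicin guideline:
once daily, 3 mg/kg for babies under 2 kg and 5 mg/kg at or above 2 kg
(the band boundary belongs to the upper band), applicable in the first 7
days of life. A prescription is `correct` when

$$(1 - m)\, d_{\text{exp}} \;\le\; d_{\text{rx}} \;\le\; (1 + m)\, d_{\text{exp}},
\qquad m = 0.20,$$

`overdose` above and `underdose` below. Design choices worth knowing:

* **Boundaries are inclusive** — a ratio of exactly 1.20 is correct ("within
  a ±20% margin" includes the margin). A relative tolerance of $10^{-9}$
  shields exact-boundary ratios from floating-point noise; tests avoid
  asserting on values inside that guard band.
* **Unassessable, not wrong.** Prescriptions past day 7, or with missing or
  non-positive weight or dose, are classified `unassessable` with a reason,
  and excluded from accuracy denominators. Judging a day-10 prescription
  against a first-week rule would be a category error; a config switch
  (`dose_rule(age_window_days = c(0, 28))`) widens the window for units
  whose guideline extends further.
* **Weight is admission birth weight** (the NAR field). Daily weights are
  not on the admission record, and dosing decisions at admission are made
  on the admission weight.
* **Frequency is audited separately.** The over/under-dose classification
  concerns the dose amount only; a frequency mismatch is a different error
  mode and is kept as its own field.

The four classes partition every prescription; `dose_accuracy_series()`
reports correct/assessable per period and weight band, with `n = 0` rows
(no estimate) for empty cells.

## The synthetic cohort

`simulate_cohort()` generates the stated world the pipeline assumes, with
defaults anchored to the published marginal structure of a high-volume
Kenyan newborn unit: about 55 abstracted admissions per month before the
April 2014 revision and about 230 after; 16.7% of admissions diagnosed
with neonatal sepsis; 9% in-hospital mortality; 46% female; birth weight
truncated-normal with mean 2.88 kg (sd 0.6 kg, bounds 0.5–5.5 kg — only
the mean is published, the spread is our choice of a clinically plausible
value); 78% of babies admitted on their date of birth and ~90% within 48
hours; a random 60% of admissions flagged for full-data abstraction; all
sepsis-diagnosed babies plus 39.5% of the others receiving gentamicin; and
dose errors planted at 4.4% overdose / 2.4% underdose. Documentation of
each variable is an independent Bernoulli draw whose probability ramps
linearly over calendar time (`default_doc_prob()`): gestational age from
0.10 to 0.80, birth weight near-universal throughout, admission temperature
and five examination signs deliberately stuck below 50% and 25% — the
documentation pathology the stratification stage is meant to surface.
Planted dose errors are multiplicative: correct doses are drawn strictly
inside the margin (ratio uniform on [0.9, 1.1]), errors strictly outside it
(the margin times a log-normal excess bounded away from 1), so the planted
rates are exactly recoverable binomial parameters.

What a green test does establish: the scoring, binning, interval and
classification machinery recovers known generating parameters at realistic
scale, end to end, deterministically under a fixed seed. What it does not:
real records correlate documentation across variables (a conscientious
clinician fills most of the form; documentation draws here are
independent), admission rates dip with strikes and seasons, dose errors
cluster by prescriber and drug stock, and transcription introduces invalid
values — none of which the generator emulates. The generator validates the
pipeline, not the hospital.

## Numerical and degenerate-input conventions

* Identical seed and parameters give byte-identical cohorts
  (`withr::with_seed`; the global RNG state is untouched).
* Report regeneration from the same inputs is byte-identical: nothing
  time-stamped is written.
* Empty denominators: explicit errors at the single-statistic level
  (`domain_completeness()`, `stratify_variable()`), `n = 0` rows at the
  table level, an explicit error for an entirely empty cohort.
* Simulated doses are rounded to 0.01 mg — at the minimum simulated weight
  the rounding error (≲0.4%) is well inside the 2% buffer that keeps
  planted errors away from the margin, so rounding can never flip a planted
  class.
* Headline summary denominators use *all* loaded records for every
  measure; published audit reports sometimes mix the combined cohort and
  an abstracted subset as denominators for different headline figures,
  which cannot be reconciled after the fact, so the report notes the
  convention in its metadata instead of imitating it.

## Known limitations

Completeness measures whether something was written, not whether it was
true — a documented-but-wrong temperature scores 1. Gestational age in this
setting is mostly anamnestic rather than ultrasound-dated, so even perfect
documentation is noisy data. The dictionary implements the 50 enumerable
variables of the standard form; units with locally extended forms should
supply their own dictionary file. And the penicillin half of first-line
sepsis treatment is not dose-audited — its dosing is weight- and
age-banded in a more complex way and is out of scope here.
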