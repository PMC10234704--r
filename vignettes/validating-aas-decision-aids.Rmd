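---
title: "Validating decision aids for acute aortic syndrome: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating decision aids for acute aortic syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rippval)
```

## The problem

Acute aortic syndrome (AAS) — aortic dissection, intramural hematoma,
penetrating atherosclerotic ulcer — is a rare, rapidly fatal emergency that
is missed on first presentation in a substantial fraction of patients.
Points-based clinical decision aids aim to stratify undifferentiated chest,
abdominal, flank or back pain into a low-risk group needing no aortic
imaging and a high-risk group needing CT. Validating such an aid on a
case-control cohort means scoring every patient with each tool and comparing
classification performance: sensitivity and specificity of the dichotomy,
discrimination of the raw ordinal score (C statistic), and how patients are
reclassified when switching tools.

This package implements that battery as a pipeline over patient-level
tabular records. Because the original chart data are not public, a seeded
synthetic cohort generator stands in for them; everything downstream is
agnostic to where the records came from.

## Data model and ingestion

A cohort is a tibble of one emergency-department presentation per row:
seventeen boolean clinical features (risk factors, pain descriptors, exam
findings, chest X-ray), a three-level clinical impression
(`alternative_likely`, `unsure`, `aas_most_likely`), demographics, a
case/control arm label (the reference standard), and two eligibility-only
fields (`pain_duration_days`, `recent_trauma_24h`). CSV ingestion accepts
`1/0`, `true/false`, `yes/no` booleans case-insensitively and treats empty
cells as missing.

**Missing data.** Chart review defaulted missing values to negative to bias
sensitivity downwards; `apply_missing_policy()` encodes exactly that: missing
booleans become `FALSE`. For the three-level impression, which has no
"negative", the neutral zero-point level `unsure` is the analogue — it is the
only choice that leaves the total score identical to leaving the category
unscored. The operation is idempotent and logs per-field imputation counts.

**Eligibility.** Exclusions are applied in a fixed order — age < 18, pain
duration strictly > 14 days, trauma within 24 h, then chart-level
ineligibility — and a record failing several rules is tallied once under the
first. The order of tie-breaking is not defined by the source protocol; a
fixed printed order was chosen so exclusion tallies are reproducible. Chart
judgments that cannot be derived from the modelled fields (no documented
qualifying complaint; clear alternative diagnosis at initial assessment)
enter through an optional pre-computed `eligible` column.

**Control selection.** `select_controls()` performs the 1:1 unmatched design:
uniform sampling of controls without replacement under a dedicated seed
stream, all cases retained.

## The scorers

`score_ripp()` is the native implementation of the RIPP scorecard (see the
README table). Two conventions needed fixing:

* **Threshold at exactly 1.** The scorecard's caption defines "< 1: no
  further investigation" and "> 1: investigate", leaving a total of exactly 1
  undefined. The default here is high risk ⇔ total ≥ 1, on the rationale
  that the guideline is sensitivity-first; the alternative ≥ 2 convention is
  available as `threshold = "ge2"` and its downstream effect is exercised in
  the test suite (it can only trade sensitivity for specificity).
* **Thoracic aneurysm** counts as "aortic aneurysm" (2 points): it is a
  subtype of the risk-factor category's top level.

The four comparators run through a declarative engine. A
`score_definition` is a list of named items, each a predicate over declared
record fields restricted to conjunction, disjunction, negation and equality
tests — no arithmetic, so an encoding can be audited line by line — with
either summed item points or a count of categories containing at least one
satisfied item, dichotomised at a threshold. Definitions ship as editable
JSON under `inst/extdata/score_definitions/` and are validated at load time
(an unknown field or operator fails immediately, not during scoring). The
ADD risk score is the canonical 0–3 category count (predisposing conditions /
pain features / exam findings, high ⇔ ≥ 1); the Von Kodolitsch tool counts
aortic pain, abnormal chest X-ray, and pulse/BP differential (high ⇔ ≥ 1).
The **AORTAs and Lovy encodings are provisional**: the validation study
cites their sources without restating item lists, so the shipped JSON files
are flagged `"provisional": true` and are meant to be replaced wholesale; no
test or headline result depends on their item content. An engine-encoded
RIPP (`ripp_engine.json`) exists purely as an equivalence oracle against the
native scorer and is checked on 10,000 random records.

## The synthetic world

The generator's defaults are the stated conditions of the validation cohort:
379 cases and 379 controls; each boolean feature drawn independently per
record as Bernoulli with the published per-arm prevalence (e.g. abrupt-onset
pain 0.812 in cases vs 0.132 in controls; new murmur 0.042 vs 0); mean age
68.5 y; 52.3% female. Values the publication does not state were chosen once
and are not tuned:

* age SD 15 y, Normal truncated at 18 (only the mean is published);
* the impression distribution is pinned only at
  P(`alternative_likely`) = 0.106 (cases) / 0.298 (controls); the remaining
  mass is split `unsure` : `aas_most_likely` = 20:80 in cases and 50:50 in
  controls — uncalibrated, configurable;
* pain duration Exp(mean 1 d) truncated at 14 d and no recent trauma, so
  generated records are eligible by construction;
* the thoracic-aneurysm flag is drawn only among known-aneurysm records at
  the conditional rate implied by the two published marginals (subtype
  invariant).

**What a green test does and does not establish.** Features are independent
within arm because only marginal prevalences are published; real clinical
features are positively correlated (a dissecting patient tends to have
several findings at once), and the three-level impression is surely
correlated with everything. Consequently the simulated cohort reproduces the
published *prevalences* (checked to ±0.02 at n = 10,000 per arm) but cannot
and does not reproduce the published *accuracy table, AUCs or NRIs*, which
depend on the unavailable joint distribution. Those printed values enter the
test suite only where they are recomputable from printed inputs: the
sensitivity/specificity percentages and interval bounds follow exactly from
the printed confusion counts. Tuning the generator to match the published
accuracy values was explicitly rejected — the joint dependence is
unidentified from the publication.

## Statistical machinery

**Exact intervals.** The publication reports 95% CIs without naming the
family. Clopper–Pearson was adopted because it reproduces the printed bounds
exactly (e.g. 378/379 → 98.54–99.99), which Wilson and Wald do not; Wilson
remains available behind `method = "wilson"`. The implementation uses beta
quantiles; the test suite cross-checks it against direct numerical inversion
of the binomial tails to 1e−6 over an exhaustive grid of n ≤ 50.

**Sample size.** `required_cases()` returns the smallest n whose
normal-approximation half-width `z·sqrt(p(1−p)/n)` meets the target. At an
expected sensitivity of 0.85 and ±5% it gives 196; the publication's stated
"200 cases" is not exactly reproduced by this formula at any obvious p (the
assumed sensitivity is unstated), so the function returns the formula value
and no check claims 200.

**ROC and DeLong.** The raw ordinal scores (not the dichotomy) feed the ROC:
the published RIPP AUC (0.8284) exceeds the dichotomous (sens+spec)/2 value,
so the published curves must be multi-threshold. Ties use the midrank
convention throughout; `empirical_auc()` computes the Mann–Whitney statistic
and DeLong structural components via midranks, and `delong_compare()` builds
the variance of a paired AUC difference from the 2×2 component covariance
(case side / m + control side / n), with a normal-approximation CI and no
continuity correction. Degenerate inputs are defined explicitly: a tool
compared with itself gives difference 0, variance 0, p = 1; zero variance
with a nonzero difference is reported as p = 0 with a `degenerate` flag and
a warning. The published pairwise AUC table is *not* a reproduction target —
its values need patient-level scores — and its signed differences are
labelled ambiguously in the source, so the output names both operands
explicitly (`difference = auc_baseline − auc_tool`).

**NRI.** The per-arm (event/non-event) convention is used: the published
reclassification table's two signed columns attribute arms ambiguously, so
the implementation reports the full four-proportion decomposition with
explicit arm labels instead, plus overall NRI. Whether the source's
"absolute NRI" divides by arm sizes or total n is not stated; the per-arm
convention was implemented and flagged. NRI p-values are out of scope
(no inference method is described for them in the source). Record-wise and
table-derived NRI are checked against each other exhaustively, and overall
NRI is antisymmetric under swapping baseline and candidate.

## Numerical and engineering choices

* One global seed fans out to the generator and the control sampler through
  independent derived streams (multiplicative congruential step, kept below
  2^31), so toggling one stage does not shift another's draws; reports are
  byte-identical across runs at a fixed seed and carry a provenance block
  (package version, seed, config) with no timestamps.
* Table cells render as percentages to 2 decimals with half-up rounding,
  matching the published formatting (`99.74 (98.54-99.99)`).
* Score definitions were specified as YAML in the original design; no YAML
  parser is available in this R stack, so the declarative files are JSON
  with identical structure.
* DeLong calibration is verified rather than assumed: its variance is
  checked against a 2,000-replicate bootstrap on a seeded 200-per-arm
  cohort (within 10%), and its type-I error against 500 null cohorts built
  from two exchangeable, correlated score columns with identical marginals
  (empirical size ≤ 0.07 at nominal 0.05). The literal "same column
  relabelled" null is degenerate (zero variance), hence the exchangeable
  construction.

## Known limitations

* Within-arm feature independence in the generator (see above); an optional
  shared-severity correlation parameter was considered and deliberately left
  out of scope since no correlation structure is published to calibrate it.
* AORTAs and Lovy encodings are provisional placeholders (flagged in their
  JSON) pending the authoritative item lists.
* Case-control sampling means absolute risks, predictive values and
  prevalence-adjusted quantities are not estimable and are intentionally not
  computed.
* The package reproduces the published accuracy table only from its printed
  counts; AUC and NRI values printed in the source require the original
  patient-level data and are outside what any simulation here can verify.
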