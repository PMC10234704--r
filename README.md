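# rippval

Validation machinery for clinical decision aids for **acute aortic syndrome
(AAS)** — aortic dissection, intramural hematoma, and penetrating
atherosclerotic ulcer. AAS is rare, lethal, and frequently missed at first
presentation; points-based decision aids are meant to tell clinicians who
needs aortic imaging. This package implements, for biostatisticians and
emergency-medicine researchers, the full comparative diagnostic-accuracy
battery used to validate such an aid on a case-control cohort:

* the **RIPP score** (Risk factors, Impression, Physical exam, Pain) scored
  natively, and four comparator tools (ADD risk score, Lovy, Von Kodolitsch,
  AORTAs) run through a declarative, auditable predicate engine with editable
  JSON encodings;
* a seeded **synthetic case-control cohort generator** whose per-arm feature
  prevalences are calibrated to the published cohort characteristics
  (379 cases / 379 controls by default), so every downstream stage is
  testable without any chart data;
* **accuracy statistics**: TP/FN/TN/FP, sensitivity and specificity with
  exact Clopper–Pearson intervals, precision-based sample-size calculation;
* **ROC/AUC comparison**: the empirical C statistic
  `AUC = (1/mn) Σᵢⱼ [1(xᵢ>yⱼ) + ½·1(xᵢ=yⱼ)]` on the raw ordinal scores, with
  paired **DeLong** tests of correlated AUC differences via structural
  components;
* **net reclassification**: per-arm NRI
  `NRI = (P(up|case) − P(down|case)) + (P(down|control) − P(up|control))`
  with full reclassification tables.

## The RIPP score

| Category | Finding | Points |
|---|---|---|
| Risk factor | none / non-aneurysmal risk factor / known aortic aneurysm | 0 / 1 / 2 |
| Impression | alternative likely / unsure / AAS most likely | −1 / 0 / +2 |
| Physical exam | any of hypotension, new murmur, pulse deficit, focal neuro deficit, BP differential >20 mmHg | +2 |
| Pain | 0 / 1–2 / >2 high-risk features (abrupt, tearing, migrating, severe) | 0 / 1 / 2 |

Totals range over [−1, 8]; the default convention classifies **high risk at
total ≥ 1** (a `ge2` switch is provided, see the vignette).

## Worked example

The numbered scripts under `analysis/` run the whole validation on the
simulated cohort (`Rscript analysis/01_simulate_cohort.R` … `06_full_report.R`),
or equivalently in one call:

```r
library(rippval)
report <- run_pipeline(run_config(input = "synthetic", seed = 20230525L))
cat(render_report(report, "text"), sep = "\n")
```

```
Cohort: 379 cases / 379 controls; mean age 68.7; 51.8% female

Tool               TP   FN   TN   FP  Sensitivity            Specificity               AUC
ripp              369   10  182  197  97.36 (95.20-98.73)    48.02 (42.89-53.18)    0.8989
addrs             349   30  262  117  92.08 (88.89-94.60)    69.13 (64.21-73.75)    0.8677
lovy              262  117  373    6  69.13 (64.21-73.75)    98.42 (96.59-99.42)    0.9346
aortas            209  170  364   15  55.15 (49.98-60.23)    96.04 (93.56-97.77)    0.8762
von_kodolitsch    273  106  372    7  72.03 (67.22-76.49)    98.15 (96.23-99.25)    0.8522

AUC differences (ripp minus tool, DeLong):
  addrs            diff +0.0312 (+0.0057 to +0.0567), p = 0.01629
  ...
```

Each row is one tool's confusion counts on the simulated cohort, its
sensitivity/specificity as percentages with exact 95% intervals, and the AUC
of its raw (multi-threshold) score; the comparison block gives the paired
DeLong difference of each comparator's AUC against the RIPP score. On this
synthetic world the RIPP score is, as designed, the most sensitive and least
specific tool. Cell values depend on the seed; the published accuracy table
itself is reproduced exactly from its printed confusion counts by
`analysis/03_accuracy_tables.R` (e.g. RIPP `99.74 (98.54-99.99)`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch at the given seed — generator,
missing-data resolution, eligibility exclusions, 1:1 control selection,
all five scorers, and the accuracy/AUC/NRI battery — and writes its JSON
output to `--out`.
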