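# pedtriage

Five-level pediatric emergency triage: a rule-based classifier and the
full validation toolkit around it.

Emergency departments sort arriving children into ordered urgency levels
(1 = most urgent, 5 = least) under time pressure and with age-dependent
norms: a heart rate that is alarming in a twelve-year-old is normal in an
infant. `pedtriage` implements a five-level pediatric triage instrument
that combines

* a **Pediatric Assessment Triangle (PAT)** gate — any abnormal arm
  (appearance, work of breathing, circulation to skin), or the need for an
  immediate life-saving intervention, mandates **level 1** (seen
  immediately);
* a **high-risk / vital-sign** screen — any high-risk situation code or any
  recorded vital outside its age-banded reference range places **level 2**
  (seen within 10 minutes);
* an **ESI-style resource ladder** — predicted need for ≥ 2 resources is
  **level 3** (within 60 minutes), one resource **level 4**, none
  **level 5** (no guaranteed waiting time).

It is aimed at emergency-medicine and nursing researchers who develop or
validate triage instruments, and ships everything needed to evaluate one
against outcomes:

* **Adjudication** of each encounter as appropriate, over-triaged
  (urgent level but < 2 resources used / level 1 not admitted) or
  under-triaged (missed PAT/LSI/vitals/high-risk criteria, or level 4–5
  with ≥ 2 resources or admission), with under-triage evaluated first;
* **Screening metrics** treating "level 1–3" as a screen for
  admission-or-ED-death: sensitivity = TP/(TP+FN), specificity =
  TN/(TN+FP), PPV, NPV, each with exact (Clopper–Pearson) or Wilson
  confidence intervals;
* **Factor odds ratios** for appropriateness, OR = ad/bc with Woolf
  log-normal intervals exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d));
* a **synthetic cohort generator** — a stochastic mode with configurable
  per-level margins driven by a counter-based RNG, and a deterministic
  520-encounter replay fixture whose published margins are exact — so the
  entire pipeline runs and is tested with no patient data.

## Worked example

```r
library(pedtriage)

cohort <- replay_fixture()          # deterministic 520-encounter cohort
res <- spt_validate(cohort)         # classify is implicit: levels present
print(res)
```

```
Screening performance (clopper_pearson 95% CI)
  sensitivity   98.28% (93.91-99.79)  [114/116]
  specificity   26.24% (22.01-30.82)  [106/404]
  ppv           27.67% (23.40-32.26)  [114/412]
  npv           98.15% (93.47-99.77)  [106/108]
Adjudication of 520 encounters
  appropriate   357 (68.7%)
  over          149 (28.7%)
  under          14 (2.7%)
...
Factor odds ratios for appropriate triage (Woolf 95% CI):
  underlying_resp_disease   4.16 (1.75-9.93)
  fever                     0.60 (0.41-0.88)
  dyspnea                   6.38 (2.51-16.22)
  ...
```

Reading: of the 116 children admitted (or who died in the ED), 114 had
been placed in an urgent level — the instrument almost never misses a
truly urgent child (sensitivity 98.28%, NPV 98.15%) — while the low
specificity (26.24%) is the mirror of its 28.7% over-triage rate: many
non-urgent children are placed in urgent levels, which is the accepted
safety trade-off. Dyspnea and wheezing carry odds ratios well above 1
(easier to triage appropriately); fever and diarrhea below 1 (they
inflate heart and respiratory rates, inviting over-triage).

Single encounters work too:

```r
p <- patient_presentation(18, vitals = vital_signs(spo2 = 92),
                          predicted_resources = 1)
spt_classify(p)
#> Triage level 2 (time to physician: <= 10 min)
#> Fired rules: vital_spo2_low
```

A command-line interface wraps the same functions
(`inst/scripts/triage`): `classify`, `adjudicate`, `validate`,
`simulate`, `fixture`, each reading/writing cohort CSV per the column
dictionary in `?cohort_schema`.

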