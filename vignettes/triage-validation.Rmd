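---
title: "Methods: a five-level pediatric triage instrument and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a five-level pediatric triage instrument and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedtriage)
```

## The instrument

`pedtriage` models a five-level pediatric emergency triage scale of the
family that blends the Emergency Severity Index's resource-prediction
ladder with pediatric-specific acuity gates. Classification is a strict
priority cascade; the first matching rule wins and no later rule can
de-escalate:

1. abnormal Pediatric Assessment Triangle (any of appearance, work of
   breathing, circulation to skin) **or** need for an immediate
   life-saving intervention → **level 1**, seen immediately;
2. any high-risk situation code **or** any recorded vital sign outside
   its age-band reference range → **level 2**, within 10 minutes;
3. predicted need for ≥ 2 resources → **level 3**, within 60 minutes;
4. one predicted resource → **level 4**; none → **level 5**; no
   guaranteed time, with nurse re-evaluation while waiting.

Two modelling assumptions deserve emphasis.

**One abnormal vital suffices for level 2.** Protocols of this family do
not always state whether level 2 requires one out-of-range vital or a
combination; we implement "any one", the conservative
(safety-maximising) reading, and document it here rather than hiding it
in code. Sites wanting combination rules can pre-process their high-risk
registry instead.

**Missing vitals never escalate.** Real triage charts have unrecorded
vitals (a few percent of saturations in a typical pediatric ED cohort),
and those children were still triaged. An unmeasured vital is treated as
absent evidence, not abnormality. `spt_classify(..., strict = TRUE)`
appends an `unmeasured_vitals` marker to the rationale so such
presentations can be routed to re-triage without distorting the level.

## Tunable parameters

The engine hard-codes no clinical numbers. An `spt_config` bundles:

* the **vital-sign reference table**: closed-open age bands `[low, high)`
  in months tiling `[0, 180)` — six PaedCTAS-style bands by default
  (0–3 mo, 3–12 mo, 1–3 y, 3–6 y, 6–12 y, 12–15 y) — and, per band,
  closed acceptance ranges `[low, high]` for temperature (°C), heart
  rate (/min), respiratory rate (/min), systolic blood pressure (mmHg)
  and SpO₂ (%). The bundled numbers are conventional pediatric norms
  labelled *editable default* in the file's provenance field: the exact
  cutoffs belong to each site's protocol, and nothing downstream of
  classification depends on them. Boundary values are deliberately
  *within* range (closed acceptance intervals): a heart rate exactly at
  the band limit is clinically "within normal limits", and the tests pin
  this with a boundary sweep against a brute-force range check.
* the **high-risk registry** and **life-saving-intervention registry**:
  editable code lists standing in for the source protocols (ESI-style
  LSI lists, institutional septic-shock early-warning criteria). Their
  internals are out of scope; an encounter either carries a code or not.

## Adjudication

Each encounter is labelled from its assigned level, its outcome
(resources actually used; disposition discharge / ward / ICU / ED-OR,
with ED death counted alongside admission), and the retrospectively
verified presentation. Under-triage is evaluated **before** over-triage —
a level-2 encounter could in principle match both, and the patient-safety
reading resolves the tie toward under-triage.

Two rule sets are provided because the verbatim over-triage definition
("levels 1–3 that used < 2 resources") conflicts with the per-level
over-triage counts reported for the cohort this package's fixture
replays: that cohort has 91 level-2 encounters with < 2 resources but
only 63 level-2 over-triages. Exempting *admitted* level-2/3 patients
from the resource clause reproduces both per-level counts (63 and 86)
and the overall 357/149/14 split exactly, and is clinically coherent —
admission justifies an urgent level regardless of resource count. The
package therefore defaults to this `reconciled` rule set and retains
`strict_paper` (the verbatim clause) for transparency; on the replay
fixture the verbatim reading yields 328/178/14.

The truth for the level-2/3 under-triage clauses comes from the
triage-time columns overlaid with `retro_*` columns (`retro_lsi`,
`retro_pat_abnormal`, `retro_vitals_abnormal`, `retro_high_risk`). This
mirrors chart-review adjudication: the nurse's recorded assessment
justified the assigned level, and the missed criterion surfaced later.
It also resolves an otherwise contradictory pair of requirements — a
classification round-trip preserves every assigned level in the fixture,
*and* 14 encounters are under-triaged.

Percentages are reported at full precision with a half-up rounded
display value. For a 357/149/14 split the over-triage rate is
149/520 = 28.654 %, which rounds to 28.7; published roundings of this
quantity vary between 28.5 and 28.6 depending on the source section, so
the package never matches a single printed rounding and instead exposes
the unrounded value.

## Screening metrics and confidence intervals

Urgency (levels 1–3) is treated as a binary screen for
admission-or-ED-death. Proportion CIs default to **Clopper–Pearson**
(exact beta-quantile inversion of the binomial tail), with Wilson as an
option: for the fixture's sensitivity 114/116 the exact method gives
(93.91, 99.79), matching reference values where they are reproducible;
Wilson does not. The exact method is property-tested against an
independent bisection of the binomial CDF to 10⁻⁹. A metric with a zero
denominator is reported as *undefined*, never silently 0.

Published predictive-value intervals for cohorts of this shape
(e.g. 26.43–28.95 for a PPV of 114/412) are not reproducible by any
standard binomial method we know of; the package documents this and does
not attempt to match them.

Odds ratios use the **Woolf** log-normal interval, which reproduces every
reproducible reference interval from the corresponding 2×2 counts at two
decimals. With a zero cell the OR is undefined unless the
Haldane–Anscombe 0.5 correction is explicitly enabled, in which case the
result is flagged `corrected`. Denominator policy is per factor:
observational factors (complaints, auscultation findings, underlying
disease) use the full cohort; factors derived from a recorded vital
(SpO₂ < 95 %) are tabulated among encounters with that vital recorded —
the only combination consistent with the reference intervals.

## The synthetic cohort

### Replay fixture

`replay_fixture()` builds a 520-encounter cohort, in code and without
random numbers, whose published margins are exact: level sizes
10/247/155/100/8; the level × resources-used and level × disposition
cross-tabs; the reconciled adjudication profile (357 appropriate, 63/86
over-triaged in levels 2/3, 3/1/10 under-triaged in levels 2/3/4); and
the factor × appropriateness cross-tabs behind the odds ratios,
including saturation recorded for 339/157 encounters.

Joint cells the margins do not pin down are filled by fixed conventions,
chosen once and documented here rather than presented as data:

* encounters are laid out in contiguous blocks per
  (level × adjudication group × resource group × disposition); admitted
  patients are placed preferentially in the higher-resource groups;
* binary factors are assigned cyclically within each appropriateness
  stratum, each factor at its own fixed offset so factors decorrelate;
  chief complaints and work shifts fill contiguous segments;
* the 3 level-2 under-triages are the level-2 ICU admissions and carry
  `retro_lsi` (consistent with diagnoses like anaphylaxis and septic
  shock); the single level-3 under-triage is a discharged one-resource
  encounter with `retro_high_risk`; the 10 level-4 under-triages are its
  ≥ 2-resource users, 2 of them the level-4 ward admissions;
* desaturations (SpO₂ 92 %) are placed on level-2 encounters only, so
  every level-2 row has exactly one gate (a desaturation or a high-risk
  code) and the classification round-trip preserves all 520 levels;
  missing saturations are placed on level-3/4 rows so no gate is lost;
* ages follow a per-stratum piecewise-linear quantile ladder with median
  36 months and quartiles 12 and 84, matching the reference demography
  in both strata;
* the respiratory-underlying-disease cross-tab is not published; the
  fixture uses 49 appropriate / 6 inappropriate carriers — the unique
  counts (within the published "any underlying disease" margins of
  93/29) whose sample OR rounds to the reported 4.16 and whose Woolf
  lower bound is exactly the reported 1.75. The reported upper bound
  (9.23) is not reproducible from any integer cross-tab under Woolf,
  Gart-corrected or Fisher intervals (these counts give 9.93); the
  fixture is therefore labelled a synthetic convention for this factor
  and the interval is not an acceptance surface.

An equivalent way to produce such a fill is iterative proportional
fitting to the known margins followed by largest-remainder rounding;
because every constrained margin here is either per-level categorical or
binary-by-stratum, the block-and-offset construction reaches the same
guarantee (all published margins exact, everything else reproducible
convention) with far less machinery, and is bit-stable by construction —
a golden-margin test freezes per-column checksums.

### Stochastic mode

`generate_cohort(cohort_spec(...))` draws cohorts with configurable
margins, defaulting to the replay cohort's calibration: level weights
10/247/155/100/8 out of 520, the per-level resource-use and admission
margins above, 53.7 % boys, log-normal ages (meanlog log 36; sdlog 1.4,
a compromise between the asymmetric implied quartile spreads, truncated
to < 180 months), 4.6 % missing saturation, and a 30/247 chance that a
level-2 encounter's gate is a desaturation rather than a high-risk code.
In `consistency = 1` mode (default) every presentation is generated so
classification recovers the sampled level.

Randomness is **counter-based**: every sampled value is
`hash(seed, encounter_id, field)` through a murmur3-finalizer hash in
exact 32-bit double arithmetic. Consequently the same seed reproduces a
cohort byte-for-byte, a cohort of size 120 is exactly the first 120 rows
of a cohort of size 300, and adding sampled fields never perturbs
existing ones. The field registry is append-only for that reason.

What the generator emulates: the margins above, marginal factor
prevalences, and level-consistent presentations. What it does not
emulate: arrival-time/queueing processes, correlations between factors
within an encounter (a generated febrile infant is no more tachycardic
than an afebrile one — in-range vitals are drawn within the middle half
of the band), nurse behaviour, or crowding dynamics. Tests that pass on
synthetic cohorts therefore validate the *pipeline arithmetic*, not the
clinical performance of the instrument on real children.

## Numerical choices and degenerate inputs

* Age bands closed-open, acceptance ranges closed (boundaries in range).
* Vitals must be positive and SpO₂ ≤ 100; violations are input errors,
  not abnormality flags. Missingness is explicit `NA` / empty CSV field,
  never 0.
* An ED death with disposition "discharge" is rejected as inconsistent.
* Rationale order is canonical (PAT arms, then LSI; vitals in fixed
  order before sorted high-risk codes) so identical inputs give
  identical results including rationale.
* Display rounding is half-up; all internal arithmetic is full
  precision.
* Empty levels in summary tables render undefined percentages as
  missing, not 0.

## Problem sizes

The property suites run on 10⁴ randomized presentations and 10⁴
randomized adjudication inputs; the stochastic calibration check draws
10⁴ encounters per level and requires empirical resource and admission
margins within 3 Monte-Carlo standard errors of their spec values, with
degenerate (0/1) margins holding exactly. These sizes make the binomial
tolerances tight enough to catch real calibration defects while keeping
the full suite around ten seconds on one CPU.

## Known limitations

* The bundled vital-sign cutoffs and registries are editable defaults,
  not a clinical standard; deployments must supply their own protocol.
* Unadjusted odds ratios only; no multivariable adjustment.
* Inter-rater reliability of the instrument (scenario-based κ) is not
  modelled: the scenarios behind such estimates are not published.
* The crowding indicator is a boolean input; crowding-score internals
  are out of scope.
* Time targets are annotations; no waiting-time simulation.
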