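# Default triage configuration.
#
# provenance: editable default. Age bands and acceptable vital-sign ranges
# follow the PaedCTAS-style pediatric age groups; the numeric cutoffs are
# conventional pediatric norms and are meant to be replaced by each site's
# own reference table. Nothing downstream of classification depends on the
# specific numbers, only on the table's structure.
#
# Age bands are closed-open intervals [low, high) in months and must tile
# [0, 180) with no gaps or overlaps. Acceptable ranges are closed intervals:
# a recorded value exactly at a bound counts as within range.
provenance: "editable default (PaedCTAS-style age bands, conventional norms)"
age_bands:
  - {low: 0,   high: 3,   label: "0-3 mo",
     heart_rate: [100, 180], respiratory_rate: [30, 60],
     systolic_bp: [60, 110], temperature: [36.0, 38.0], spo2: [95, 100]}
  - {low: 3,   high: 12,  label: "3-12 mo",
     heart_rate: [90, 160],  respiratory_rate: [25, 50],
     systolic_bp: [70, 110], temperature: [36.0, 38.0], spo2: [95, 100]}
  - {low: 12,  high: 36,  label: "1-3 y",
     heart_rate: [80, 150],  respiratory_rate: [20, 40],
     systolic_bp: [75, 115], temperature: [36.0, 38.0], spo2: [95, 100]}
  - {low: 36,  high: 72,  label: "3-6 y",
     heart_rate: [70, 140],  respiratory_rate: [20, 30],
     systolic_bp: [80, 120], temperature: [36.0, 38.0], spo2: [95, 100]}
  - {low: 72,  high: 144, label: "6-12 y",
     heart_rate: [60, 120],  respiratory_rate: [14, 24],
     systolic_bp: [85, 130], temperature: [36.0, 38.0], spo2: [95, 100]}
  - {low: 144, high: 180, label: "12-15 y",
     heart_rate: [60, 100],  respiratory_rate: [12, 20],
     systolic_bp: [90, 140], temperature: [36.0, 38.0], spo2: [95, 100]}
# High-risk situations eligible to place a patient in level 2. Editable
# registry: sites append their own protocol codes (e.g. institutional
# septic-shock early-warning criteria are represented as codes here, their
# internals are out of scope).
high_risk_registry:
  - hr_sepsis_warning
  - hr_severe_pain
  - hr_immunocompromised_fever
  - hr_ingestion_or_poisoning
  - hr_neonatal_fever
  - hr_altered_mental_state
  - hr_significant_mechanism_injury
# Immediate life-saving interventions whose need mandates level 1.
lsi_registry:
  - lsi_airway_support
  - lsi_bag_valve_mask
  - lsi_defibrillation
  - lsi_fluid_resuscitation_shock
  - lsi_emergency_medication
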