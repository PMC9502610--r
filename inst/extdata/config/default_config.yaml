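# Default phenotype configuration.
#
# Code sets are documented stand-ins built from standard ICD-10-AM chapter
# prefixes, ICPC-2 rubrics and ATC classes; production deployments are
# expected to override them with locally curated lists (see `load_config`).
# Matching is by prefix, case-insensitive and dot-insensitive.
version: 1

code_sets:
  ckd_related:
    icd10am: [N18, N19, N02, N03, N04, N05, N07, N08, N11, N14, N15, N16, Q61,
              Z49, Z940, Z992]
    icpc2: [U99, U88]
  aki:
    icd10am: [N17]
    icpc2: []
  rrt_dialysis:
    icd10am: [Z49, Z992]
    icpc2: [U59]
    icd10am_procedure: ["13100"]
    mbs: ["13100", "13103"]
  rrt_haemodialysis:
    icd10am: [Z491]
    icpc2: []
    icd10am_procedure: ["13100"]
    mbs: ["13100"]
  rrt_peritoneal_dialysis:
    icd10am: [Z492]
    icpc2: []
    icd10am_procedure: ["13103"]
    mbs: ["13103"]
  rrt_transplant:
    icd10am: [Z940]
    icpc2: []
    icd10am_procedure: ["36503"]
    mbs: ["36503"]
  t2dm:
    icd10am: [E11]
    icpc2: [T90]
  hypertension:
    icd10am: [I10, I11, I12, I13, I15]
    icpc2: [K86, K87]
  cvd:
    icd10am: [I20, I21, I22, I23, I24, I25, I60, I61, I62, I63, I64, I65, I66, I67, I68, I69]
    icpc2: [K74, K75, K76, K89, K90, K91]
  glucose_lowering_med:
    atc: [A10]
  antihypertensive_med:
    atc: [C02, C03, C07, C08, C09]
  chronic_disease_med:
    atc: [A10, C01, C02, C03, C07, C08, C09, C10, B01]

# Codes that imply a specific CKD stage (1..5) for the administrative-code
# comparator and for code-only staging when laboratory staging is impossible.
# ICPC entries are ICPC-2 PLUS style extension codes (synthetic stand-ins).
stage_codes:
  icd10am:
    N181: 1
    N182: 2
    N183: 3
    N184: 4
    N185: 5
  icpc2:
    U9901: 1
    U9902: 2
    U9903: 3
    U9904: 4
    U9905: 5

thresholds:
  # KDIGO G-stage boundaries, mL/min/1.73m2 (G1 >= 90 ... G5 < 15)
  g_stage_boundaries: [90, 60, 45, 30, 15]
  # KDIGO A-stage boundaries, mg/mmol (A1 < 3; A2 3-30; A3 > 30)
  a_stage_boundaries: [3, 30]
  # chronicity rule for reduced eGFR
  egfr_low_threshold: 60
  egfr_persistence_days: 90
  require_latest_low: true
  # albuminuria persistence
  uacr_elevated: 3
  uacr_min_count: 2
  uacr_min_span_days: 0
  uacr_stringent_span_days: 90
  # which eGFR feeds the stage label once chronicity is established
  staging_aggregate: latest   # latest | median
  # diabetes
  hba1c_elevated: 48          # mmol/mol (6.5%)
  hba1c_min_count: 2
  # hypertension (clinic BP, mmHg)
  bp_systolic: 140
  bp_diastolic: 90
  bp_min_count: 2
  # maintenance-dialysis (episodic-dialysis guard)
  dialysis_maintenance_count: 3
  dialysis_maintenance_window_days: 90
  # at-risk flag: externally supplied five-year cardiovascular risk, percent
  cvd_risk_cutoff: 15

# CKD-EPI creatinine equation coefficients (2009, no race term),
# serum creatinine in umol/L. Swap this block for the 2021 refit if needed.
ckd_epi:
  version: "2009"
  kappa_female: 61.9
  kappa_male: 79.6
  alpha_female: -0.329
  alpha_male: -0.411
  exponent_above_kappa: -1.209
  age_factor: 0.993
  female_multiplier: 1.018
  scale: 141
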