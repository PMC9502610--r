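---
title: "Electronic phenotyping of CKD and comorbidities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electronic phenotyping of CKD and comorbidities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdphen)
```

## The problem

Administrative diagnosis codes under-detect chronic kidney disease (CKD):
early disease is clinically silent, and even late-stage disease is often
never coded. Rule-based *electronic phenotype algorithms* combine codes with
laboratory values and medications to classify patients as disease positive
or negative from routinely collected, linked electronic health records
(EHR). `ckdphen` implements such algorithms for CKD (with full KDIGO
staging), renal replacement therapy (RRT), type 2 diabetes, hypertension and
cardiovascular disease, together with the statistical machinery used to
validate them against chart-review gold standards and to describe the
completeness of the underlying data. Because real linked EHR data cannot be
shipped, the package also contains a ground-truth synthetic cohort generator
that emulates the structure of such a database, so every classifier and
metric is exercised end to end in the test suite.

## The CKD model

Kidney function is summarised by the estimated glomerular filtration rate
(eGFR), computed from serum creatinine with the 2009 CKD-EPI equation
without the race term — the form in which Australian laboratories report
eGFR. With creatinine $S_{cr}$ in µmol/L, sex-specific knot
$\kappa$ (61.9 female, 79.6 male) and exponent $\alpha$ (−0.329 female,
−0.411 male):

$$
\mathrm{eGFR} = 141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha}
  \cdot \max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{\mathrm{age}}
  \cdot 1.018\,[\text{female}]
$$

The coefficient block lives in the YAML configuration, so the 2021 refit can
be substituted without code changes. Kidney damage is summarised by the
urine albumin-to-creatinine ratio (uACR, mg/mmol). KDIGO G-stages bin eGFR
at 90/60/45/30/15 (lower bound inclusive); A-stages bin uACR at 3 and 30
(A2 includes both bounds).

A *chronic* reduction in eGFR requires two or more readings below
60 mL/min/1.73m² at least 90 days apart ("three months" is operationalised
as ≥ 90 days throughout). On top of that pair rule the classifier applies a
**resolved-AKI guard**: the most recent reading must itself be below the
threshold. Acute kidney injury and wide eGFR fluctuation are the classic
causes of false chronicity; requiring the latest value to remain low is the
minimal rule that stops a resolved acute episode from being labelled
chronic. The guard is configurable (`require_latest_low`) and its effect is
unit-tested with trajectories that recover.

`classify_ckd()` evaluates in strict priority order:

1. **RRT** — any dialysis or transplant code (diagnosis or procedure) makes
   the patient RRT, which is mutually exclusive with all numeric stages.
   A maintenance-dialysis *modality* label further requires at least three
   dialysis-coded events in the 90 days before the review date (the
   episodic-dialysis guard); isolated historic sessions yield RRT with
   modality "unspecified".
2. **Laboratory staging** — if the chronicity rule is satisfied, the stage
   (CKD3a–CKD5) is taken from the G-stage of the most recent eGFR.
   Otherwise persistent albuminuria (two or more uACR ≥ 3 mg/mmol) with a
   preserved most-recent eGFR stages the patient CKD1 (eGFR ≥ 90, or no
   eGFR on record) or CKD2 (60–89).
3. **Code-only** — any CKD-related diagnosis code leaves the patient
   pooled-positive; stage-implying codes (N18.1–N18.5 equivalents) supply a
   stage only when laboratory staging was impossible, because laboratory
   evidence always outranks codes.

A single elevated uACR together with a single eGFR of 60–89 is therefore
*no CKD* (G2 with unconfirmed albuminuria is not disease under the
persistence rules), and one historic elevated HbA1c among normal readings,
with no medications or codes, is *no diabetes*. Both edge cases are frozen
as tests.

### Definition variants

Three CKD definitions are exposed through `algorithm_config()` for
sensitivity analysis: the default `stage1_plus`; `stage3a_plus`, which
disables the albuminuria-only branch (the definition most prior studies
use); and `stringent_uacr`, which additionally requires the two elevated
uACR readings to be ≥ 90 days apart, for stages 1–2 only. By construction
the positives nest: `stage3a_plus` ⊆ `stage1_plus` and `stringent_uacr` ⊆
default; the suite verifies this over the full synthetic cohort. The
default (non-stringent) albuminuria rule — two elevated readings with no
span requirement — is the only reading consistent with both the
single-elevated-uACR negative example and the existence of a distinct
stringent variant; it is called out here because it is an inference, not a
printed rule.

### Comorbidity classifiers

Diabetes: two or more HbA1c ≥ 48 mmol/mol (6.5%), or any glucose-lowering
medication (ATC A10), or any diabetes code. Hypertension: any hypertension
code, any antihypertensive (ATC C02/C03/C07/C08/C09), or clinic blood
pressure ≥ 140/90 mmHg on two or more distinct dates (thresholds
config-exposed; the guideline the rule follows prints no numbers, so both
are deliberately configurable). Cardiovascular disease is code-only by
design. The at-risk flag ORs diabetes, hypertension, any renal/AKI code and
an externally supplied five-year cardiovascular risk score strictly above
15% — the score is an input, never computed here.

## Code sets

All code logic is prefix matching, case- and dot-insensitive, per coding
system (ICD-10-AM, ICPC-2, ATC, procedure codes), because those systems are
prefix-hierarchical. The shipped YAML (`inst/extdata/config/`) uses
standard chapter prefixes (N18 CKD, E11 diabetes, I10 hypertension,
I20–I25/I60–I69 cerebro-/cardiovascular, Z49/Z94.0 RRT, A10 glucose-lowering)
and is explicitly a documented stand-in: production deployments are expected
to override it with curated local lists. The ICPC-2 stage-implying entries
(U9901–U9905) are ICPC-2 PLUS-style synthetic stand-ins that exist so the
administrative-code comparator can be exercised; the package relaxes the
ICPC pattern to letter + two digits with optional extension digits for this
reason.

## Validation machinery

`confusion_counts()` / `accuracy_report()` give sensitivity, specificity,
PPV and NPV with the asymptotic (Wald) interval
$p \pm z\sqrt{p(1-p)/n}$, clipped to $[0,1]$ — chosen over Wilson or exact
intervals because the interval is zero-width at 100%, matching how such
validation results are conventionally reported; its known under-coverage is
acknowledged and bounded by a simulation test (empirical coverage for
$p=0.9$, $n=200$ within $[0.90, 0.97]$). The two-class AUC is $(Se+Sp)/2$.
One widely circulated printing of the specificity formula divides true
negatives by "true negatives and false negatives"; the package implements
the standard $tn/(tn+fp)$.

`buderer_sample_size()` plans a diagnostic-accuracy study:
$n_{Se} = \lceil z^2 Se(1-Se)/d^2 / P \rceil$,
$n_{Sp} = \lceil z^2 Sp(1-Sp)/d^2 / (1-P) \rceil$, requirement their
maximum. The ceiling is applied *after* the prevalence division: at the
conventional design point (Se 0.95, Sp 0.90, P 0.5, d 0.05, z 1.96) this
yields 146/277/277, whereas rounding before dividing would give 278. z
defaults to 1.96; the exact quantile is available via `z = NULL`.

`cohens_kappa()` is the chance-corrected agreement for inter-rater
reliability. `stage_confusion_matrix()` cross-tabulates gold and algorithm
stage over the fixed eight-level set (none, CKD1–5, RRT), and
`coded_stage_classifier()` is the administrative-code comparator: most
severe stage-implying code per system, discordant systems averaged with
`ceiling()` on the ordinal 1–5 scale. "Stage 3" maps to CKD3a, a choice the
comparator has to make because coded stage 3 does not distinguish 3a from
3b.

`subgroup_assign()` reproduces the six-way validation stratification with a
priority order (1 through 6) that the source design leaves implicit; the
order makes the subgroups a partition (a CKD3a diabetic belongs to the CKD
subgroup, not the comorbidity subgroup). Eligibility requires three or more
combined laboratory-plus-observation entries.

## Completeness metrics

Documentation (per-type proportion of patients with any entry), breadth
(0–5 of labs / observations / ICD codes / ICPC codes / medications), and
density (entries per patient-year, with the span floored at one year so a
single-visit patient is not divided by near-zero). Four nested flags
summarise per-patient completeness; only metric 4 has an externally fixed
definition (≥ 3 laboratory results, ≥ 3 observation entries, ≥ 1 coded
diagnosis, ≥ 1 medication entry). Metrics 1–3 are package defaults forming
a ladder beneath it (any entry; a lab plus a coded diagnosis; three labs
plus a code plus a medication) and are config-overridable; the ladder
property metric4 ⇒ metric3 ⇒ metric2 ⇒ metric1 is property-tested. A
"coded diagnosis" accepts either ICD or ICPC.

## The synthetic cohort generator

`generate_patient()` draws encounter dates from a Poisson process at
`visit_rate`/year (default 4) over a 1–24-year follow-up, always adding an
intake and a review-date encounter so that persistence rules are decidable
by design. The eGFR trajectory is linear in time — the simplest generator
whose ground truth is analytically known — and creatinine is back-solved
through the closed-form inverse of CKD-EPI, then perturbed with
multiplicative lognormal noise (default CV 5%, the level at which staging
is demonstrably robust: 8-level stage agreement stays above 90% with
adjacent-stage confusion only). uACR is lognormal about its profile level.
Coding imperfection is per-disease Bernoulli emission (default sensitivity
0.9, specificity 1.0), which reproduces the qualitative phenomenon that
code-dependent phenotypes — cardiovascular disease above all, being
code-only — degrade first as coding sensitivity falls. An optional AKI
spike flag inserts a resolving creatinine doubling to exercise the
resolved-AKI guard.

`generate_validation_cohort()` reproduces the six-subgroup validation
census (default {50, 49, 51, 50, 45, 43}, total 288). It generates
noise-free by default — zero laboratory noise, perfect coding — because its
purpose is exact-recovery testing: under those conditions every classifier
attains sensitivity and specificity 1.0 against ground truth and the stage
confusion matrix is diagonal, which the acceptance suite asserts. Two
structural consequences of the priority-ordered subgroup definitions are
worth noting: any at-risk, CKD-negative patient lands in subgroup 1, so
subgroup 5/6 members must be CKD pooled-positive via an unstaged renal code;
and subgroup 6 members carry their comorbidity evidence as medications
only, since two coded comorbidities would put them in subgroup 5.

What the generator does *not* emulate: correlated disease progression,
realistic inter-visit correlation, coding drift over time, free-text
evidence, or population prevalence structure. Passing the perfect-recovery
and degradation tests therefore demonstrates internal correctness of the
rules and machinery, not field performance on real EHR data — on real data,
chart-review validation remains necessary.

## Numerical and degenerate-input choices

* eGFR values are reported rounded to 1 decimal place; stage binning is
  lower-bound inclusive, so ties at a boundary are deterministic.
* Dates are day-resolution; same-day entries keep stable input order, and a
  same-day creatinine takes precedence over a reported eGFR.
* Reported eGFR "> 90" is stored as 90 with an above-limit censor flag;
  censored-above points never count as below a threshold.
* Empty series yield `satisfied = FALSE` chronicity evidence, never errors;
  zero confusion denominators yield flagged-undefined metrics, never NaN.
* Ingest is drop-and-count: `rows_read = loaded + dropped` per table, with
  per-reason counts in the ingest report. Unit conversion happens only at
  ingest (creatinine mg/dL × 88.4; uACR mg/g ÷ 8.84), so all downstream
  logic is unit-free.
* `degrade()` subsamples exact counts (hypergeometric, not Bernoulli) so
  tests on thinned cohorts are deterministic.

## Problem sizes in the test suite

The suite runs the brute-force CKD oracle against 10,000 random small
records (plus exhaustive pair-enumeration checks of the chronicity rule on
all below/above patterns of series up to length 8), exact recovery on the
288-patient cohort, noise robustness on 400 patients at 5% creatinine CV,
coding-degradation monotonicity at three sensitivity settings × 150
patients, and 5,000-replicate Wald coverage — sizes chosen to make the
statistical assertions stable under their fixed seeds while keeping a full
run in a few minutes.

## Known limitations

Pediatric and cystatin-C eGFR equations are out of scope, as are record
linkage, FHIR/HL7 parsing, free-text fields, type 1/gestational diabetes
subtyping and the KDIGO combined G×A risk grid (G and A stages are emitted;
the grid is presentation). Whether a production system should stage from
the most recent eGFR or an aggregate of recent values is genuinely open;
most-recent is the default and a median aggregate is available via
`staging_aggregate` in the configuration. Code-only CKD positives receive a
stage only when a stage-implying code exists; otherwise they are
pooled-positive, unstaged.
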