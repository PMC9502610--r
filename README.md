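# ckdphen

Electronic phenotype algorithms for chronic kidney disease (CKD) and its
common comorbidities over linked longitudinal electronic health records
(EHR), plus the machinery to validate them.

Administrative diagnosis codes alone miss most early CKD and a surprising
amount of late CKD; combining codes with laboratory values and medications
is the accepted remedy. `ckdphen` is for epidemiologists and health-data
scientists who need to (a) classify patients from flat per-entity EHR
extracts, (b) quantify how well such rule-based classifiers agree with a
chart-review gold standard, and (c) report how complete the underlying data
are. Because linked clinical data cannot be distributed, the package ships
a ground-truth synthetic cohort generator that emulates the structure of a
regional CKD registry, so everything can be exercised end to end offline.

## What it implements

* **Renal function** — the 2009 CKD-EPI creatinine equation (no race term;
  creatinine in µmol/L, coefficients configurable), KDIGO G-staging
  (eGFR cut-offs 90/60/45/30/15, lower bound inclusive) and A-staging
  (uACR 3 and 30 mg/mmol), and temporal persistence rules: chronic eGFR
  reduction requires two readings < 60 mL/min/1.73m² at least 90 days apart
  *and* a still-low most recent reading (resolved-AKI guard).
* **Phenotypes** — pooled CKD and stage (none, CKD1–CKD5, RRT; RRT is
  mutually exclusive with numeric stages and dominates), RRT modality with
  an episodic-dialysis guard, type 2 diabetes (2+ HbA1c ≥ 48 mmol/mol, or
  ATC A10 medication, or code), hypertension (code, antihypertensive, or
  BP ≥ 140/90 on 2+ distinct dates), cardiovascular disease (code-only),
  an at-risk flag, and three CKD definition variants for sensitivity
  analysis (`stage1_plus`, `stage3a_plus`, `stringent_uacr`).
* **Validation** — confusion counts; sensitivity/specificity/PPV/NPV with
  asymptotic (Wald) 95% intervals, `p ± z√(p(1−p)/n)`; Cohen's kappa; the
  Buderer diagnostic-accuracy sample size
  `n = max{⌈z²Se(1−Se)/d²/P⌉, ⌈z²Sp(1−Sp)/d²/(1−P)⌉}`; an 8-level stage
  confusion matrix; six-subgroup validation-cohort stratification and
  seeded stratified sampling; and an administrative-code stage comparator
  (discordant ICD/ICPC stages averaged with ceiling).
* **Completeness** — documentation, breadth and density metrics, a
  2-year activity filter, and four nested per-patient completeness flags.
* **Synthetic cohorts** — profile-driven patient generation with creatinine
  back-solved through the inverse CKD-EPI relation, Bernoulli coding
  imperfection, exact-count degradation, and a 288-patient six-subgroup
  validation cohort with known ground truth.

All user-facing functions take a data frame (or `ehr_cohort`) first and
return tibbles; results have `tidy()`/`glance()` methods and `autoplot()`
where a plot is natural. Code sets and thresholds live in one YAML
configuration with documented, overridable defaults.

## Worked example

```r
library(ckdphen)

sim <- generate_validation_cohort(seed = 42)   # noise-free, known truth
sim$cohort
#> <ehr_cohort> 288 patients
#>   labs          27444 entries
#>   observations  18296 entries
#>   codes         752 entries
#>   medications   339 entries
#>   procedures    8 entries

labels <- classify_cohort(sim$cohort, algorithm_config(as_of = "2021-02-07"))
dplyr::count(labels, ckd_stage)
#> # A tibble: 8 × 2
#>   ckd_stage     n
#>   <fct>     <int>
#> 1 none        138
#> 2 CKD1         16
#> 3 CKD2         17
#> 4 CKD3a        16
#> 5 CKD3b        25
#> 6 CKD4         26
#> 7 CKD5         25
#> 8 RRT          25

tidy(accuracy_report(confusion_counts(
  stats::setNames(sim$truth$ckd_pooled, sim$truth$patient_id),
  stats::setNames(labels$ckd_pooled, labels$patient_id))))
#> # A tibble: 4 × 6
#>   metric      estimate conf.low conf.high     n undefined
#>   <chr>          <dbl>    <dbl>     <dbl> <int> <lgl>
#> 1 sensitivity        1        1         1   238 FALSE
#> 2 specificity        1        1         1    50 FALSE
#> 3 ppv                1        1         1   238 FALSE
#> 4 npv                1        1         1    50 FALSE
```

The cohort is generated noise-free, so the classifier recovers every label
exactly: sensitivity and specificity are 1 with zero-width Wald intervals
(the interval degenerates at p = 1), over 238 CKD-positive and 50
CKD-negative patients. The stage counts show the six-subgroup design: 138
patients without a numeric stage (at-risk or code-only CKD), the rest
spread across CKD1–5 and RRT. Sample-size planning for such a validation
study:

```r
buderer_sample_size(0.95, 0.90, prevalence = 0.5)
#> # A tibble: 1 × 3
#>   n_sensitivity n_specificity n_required
#>           <int>         <int>      <int>
#> 1           146           277        277
```

i.e. 277 chart-reviewed records suffice for a ±5% margin on both
sensitivity and specificity at these design expectations.

Real extracts are read with `load_cohort("dir/")` (six entity CSVs with
ISO-8601 dates; unit conversion and drop-and-count validation happen at
ingest — see `ingest_report()`). A thin command-line front end over the
same functions is in `inst/cli/phen.R` (`classify`, `validate`,
`samplesize`, `sample`, `simulate`, `completeness`).

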