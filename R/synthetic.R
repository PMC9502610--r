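.stage_targets <- c(none = 95, CKD1 = 95, CKD2 = 75, CKD3a = 52, CKD3b = 37,
                    CKD4 = 22, CKD5 = 10, RRT = 8)
.stage_slopes <- c(none = 0, CKD1 = 0, CKD2 = -0.5, CKD3a = -2, CKD3b = -2,
                   CKD4 = -3, CKD5 = -4, RRT = -4)
.stage_icd_code <- c(CKD1 = "N181", CKD2 = "N182", CKD3a = "N183",
                     CKD3b = "N183", CKD4 = "N184", CKD5 = "N185")
.stage_icpc_code <- c(CKD1 = "U9901", CKD2 = "U9902", CKD3a = "U9903",
                      CKD3b = "U9903", CKD4 = "U9904", CKD5 = "U9905")

#' Ground-truth profile for a synthetic patient
#'
#' The specification from which [generate_patient()] builds a longitudinal
#' record with analytically known phenotype labels. The eGFR trajectory is
#' linear in time, ending at a stage-typical value (e.g. 52 mL/min/1.73m2
#' for CKD3a) unless `egfr_end`/`egfr_slope` are given; serum creatinine is
#' back-solved through the inverse CKD-EPI relation with multiplicative
#' lognormal noise. Coding imperfection is modelled as per-disease Bernoulli
#' emission: a true condition is coded with probability
#' `coding_sensitivity`, a spurious code appears with probability
#' `1 - coding_specificity`.
#'
#' @param patient_id id string.
#' @param ckd_stage target stage, one of none/CKD1..CKD5/RRT.
#' @param ckd_code_only emit an unstaged CKD-related diagnosis code with no
#'   laboratory evidence of CKD (pooled-positive, stage none).
#' @param t2dm,hypertension,cvd target comorbidity status.
#' @param t2dm_channels,hypertension_channels which evidence channels carry
#'   a true comorbidity (subsets of labs/medications/codes and
#'   codes/medications/observations respectively); CVD is code-only.
#' @param sex,age_years demographics; `age_years` is age at the review date
#'   and must leave the patient adult over the whole follow-up.
#' @param followup_years longitudinal span, 1-24 years.
#' @param visit_rate expected encounters per year (a Poisson process, plus
#'   an intake and a review-date encounter).
#' @param egfr_end,egfr_slope trajectory end value (mL/min/1.73m2) and
#'   annual slope; defaults derived from `ckd_stage`.
#' @param uacr_level central uACR, mg/mmol (default 15 for CKD stages, 1
#'   otherwise).
#' @param creatinine_cv multiplicative creatinine noise (lognormal sdlog).
#' @param uacr_sigma lognormal sdlog of uACR readings.
#' @param coding_sensitivity,coding_specificity per-disease code emission
#'   probabilities.
#' @param rrt_modality for `ckd_stage = "RRT"`: haemodialysis,
#'   peritoneal_dialysis or transplant.
#' @param aki_spike insert a transient creatinine doubling mid-course that
#'   resolves (exercises the resolved-AKI guard).
#' @return a `synthetic_profile` object.
#' @export
synthetic_profile <- function(patient_id = "S0001",
                              ckd_stage = c("none", "CKD1", "CKD2", "CKD3a",
                                            "CKD3b", "CKD4", "CKD5", "RRT"),
                              ckd_code_only = FALSE,
                              t2dm = FALSE, hypertension = FALSE, cvd = FALSE,
                              t2dm_channels = c("labs", "medications", "codes"),
                              hypertension_channels = c("codes", "medications",
                                                        "observations"),
                              sex = c("female", "male"), age_years = 55,
                              followup_years = 10, visit_rate = 4,
                              egfr_end = NULL, egfr_slope = NULL,
                              uacr_level = NULL,
                              creatinine_cv = 0.05, uacr_sigma = 0.3,
                              coding_sensitivity = 0.9, coding_specificity = 1,
                              rrt_modality = c("haemodialysis",
                                               "peritoneal_dialysis", "transplant"),
                              aki_spike = FALSE) {
  ckd_stage <- match.arg(ckd_stage)
  sex <- match.arg(sex)
  rrt_modality <- match.arg(rrt_modality)
  if (followup_years < 1 || followup_years > 24) {
    stop("followup_years must lie in [1, 24]", call. = FALSE)
  }
  if (age_years - followup_years < 18) {
    stop("adult records only: age_years - followup_years must be >= 18",
         call. = FALSE)
  }
  if (visit_rate <= 0) stop("visit_rate must be positive", call. = FALSE)
  stopifnot(coding_sensitivity >= 0, coding_sensitivity <= 1,
            coding_specificity >= 0, coding_specificity <= 1,
            creatinine_cv >= 0, uacr_sigma >= 0)
  if (is.null(egfr_end)) egfr_end <- unname(.stage_targets[ckd_stage])
  if (is.null(egfr_slope)) egfr_slope <- unname(.stage_slopes[ckd_stage])
  if (is.null(uacr_level)) {
    uacr_level <- if (ckd_stage %in% c("none")) 1 else 15
  }
  if (ckd_stage %in% c("CKD1", "CKD2") && uacr_level < 3) {
    stop("infeasible profile: stage ", ckd_stage,
         " requires elevated albuminuria but uacr_level = ", uacr_level,
         " is below the 3 mg/mmol threshold", call. = FALSE)
  }
  if (ckd_stage %in% c("CKD1", "CKD2") && egfr_end < 60) {
    stop("infeasible profile: stage ", ckd_stage,
         " requires preserved eGFR but egfr_end = ", egfr_end, call. = FALSE)
  }
  structure(list(patient_id = patient_id, ckd_stage = ckd_stage,
                 ckd_code_only = ckd_code_only, t2dm = t2dm,
                 hypertension = hypertension, cvd = cvd,
                 t2dm_channels = t2dm_channels,
                 hypertension_channels = hypertension_channels,
                 sex = sex, age_years = age_years,
                 followup_years = followup_years, visit_rate = visit_rate,
                 egfr_end = egfr_end, egfr_slope = egfr_slope,
                 uacr_level = uacr_level, creatinine_cv = creatinine_cv,
                 uacr_sigma = uacr_sigma,
                 coding_sensitivity = coding_sensitivity,
                 coding_specificity = coding_specificity,
                 rrt_modality = rrt_modality, aki_spike = aki_spike),
            class = "synthetic_profile")
}

# entity tables + truth row for one profile (uses the current RNG stream)
.generate_entities <- function(p, as_of) {
  as_of <- as.Date(as_of)
  span_days <- round(p$followup_years * 365.25)
  start <- as_of - span_days
  n_mid <- stats::rpois(1, p$visit_rate * p$followup_years)
  visits <- sort(unique(c(start + 1, start + sample.int(span_days - 1, min(n_mid, span_days - 2)),
                          as_of)))
  t_years <- as.numeric(visits - start) / 365.25
  ages <- p$age_years - p$followup_years + t_years
  egfr_true <- p$egfr_end + p$egfr_slope * (t_years - p$followup_years)
  egfr_true <- pmax(egfr_true, 2)
  scr <- ckd_epi_inverse(p$sex, ages, egfr_true)
  if (p$aki_spike) {
    mid <- which(t_years > p$followup_years * 0.4 & t_years < p$followup_years * 0.6)
    scr[utils::head(mid, 2)] <- scr[utils::head(mid, 2)] * 2.5
  }
  if (p$creatinine_cv > 0) scr <- scr * exp(stats::rnorm(length(scr), 0, p$creatinine_cv))
  uacr <- p$uacr_level * exp(stats::rnorm(length(visits), 0, p$uacr_sigma))
  hba1c_level <- if (p$t2dm && "labs" %in% p$t2dm_channels) 60 else 38
  bp_high <- p$hypertension && "observations" %in% p$hypertension_channels
  id <- p$patient_id

  labs <- dplyr::bind_rows(
    tibble::tibble(patient_id = id, analyte = "serum_creatinine",
                   value = round(scr, 1), units = "umol/L", date = visits,
                   censor = "none"),
    tibble::tibble(patient_id = id, analyte = "uacr", value = round(uacr, 2),
                   units = "mg/mmol", date = visits, censor = "none"),
    tibble::tibble(patient_id = id, analyte = "hba1c", value = hba1c_level,
                   units = "mmol/mol", date = visits, censor = "none"))
  observations <- tibble::tibble(
    patient_id = id,
    kind = rep(c("systolic_bp", "diastolic_bp"), each = length(visits)),
    value = rep(if (bp_high) c(150, 95) else c(120, 75), each = length(visits)),
    date = rep(visits, 2))

  codes <- list(); meds <- list(); procs <- list()
  mid_visit <- visits[ceiling(length(visits) / 2)]
  emit_code <- function(system, code, date, truly_present = TRUE) {
    prob <- if (truly_present) p$coding_sensitivity else 1 - p$coding_specificity
    if (stats::runif(1) < prob) {
      codes[[length(codes) + 1L]] <<- tibble::tibble(
        patient_id = id, system = system, code = code, date = date,
        setting = if (system == "ICD10AM") "hospital" else "primary_care")
    }
  }
  # comorbidity codes
  if (p$t2dm && "codes" %in% p$t2dm_channels) emit_code("ICD10AM", "E11", mid_visit)
  if (!p$t2dm) emit_code("ICD10AM", "E11", mid_visit, truly_present = FALSE)
  if (p$hypertension && "codes" %in% p$hypertension_channels) {
    emit_code("ICD10AM", "I10", mid_visit)
  }
  if (!p$hypertension) emit_code("ICD10AM", "I10", mid_visit, truly_present = FALSE)
  if (p$cvd) emit_code("ICD10AM", "I21", mid_visit)
  if (!p$cvd) emit_code("ICD10AM", "I21", mid_visit, truly_present = FALSE)
  # stage-implying renal codes (for the administrative-code comparator)
  if (p$ckd_stage %in% names(.stage_icd_code)) {
    emit_code("ICD10AM", .stage_icd_code[[p$ckd_stage]], mid_visit)
    emit_code("ICPC2", .stage_icpc_code[[p$ckd_stage]], mid_visit)
  }
  if (p$ckd_code_only) {
    # constitutive evidence, emitted unconditionally
    codes[[length(codes) + 1L]] <- tibble::tibble(
      patient_id = id, system = "ICD10AM", code = "N189", date = mid_visit,
      setting = "hospital")
  }
  # RRT evidence
  if (p$ckd_stage == "RRT") {
    if (p$rrt_modality == "transplant") {
      codes[[length(codes) + 1L]] <- tibble::tibble(
        patient_id = id, system = "ICD10AM", code = "Z940", date = mid_visit,
        setting = "hospital")
      procs[[length(procs) + 1L]] <- tibble::tibble(
        patient_id = id, system = "ICD10AM_procedure", code = "36503",
        date = mid_visit)
    } else {
      code <- if (p$rrt_modality == "haemodialysis") "Z491" else "Z492"
      # maintenance pattern: weekly sessions through the last 90 days
      session_dates <- as_of - seq(0, 84, by = 7)
      codes[[length(codes) + 1L]] <- tibble::tibble(
        patient_id = id, system = "ICD10AM", code = code,
        date = sort(session_dates), setting = "hospital")
    }
  }
  # medications
  if (p$t2dm && "medications" %in% p$t2dm_channels) {
    meds[[length(meds) + 1L]] <- tibble::tibble(patient_id = id,
                                                atc_code = "A10BA02", date = mid_visit)
  }
  if (p$hypertension && "medications" %in% p$hypertension_channels) {
    meds[[length(meds) + 1L]] <- tibble::tibble(
      patient_id = id, atc_code = c("C03CA01", "C07AB02"),
      date = mid_visit)
  }

  truth <- tibble::tibble(
    patient_id = id,
    ckd_stage = p$ckd_stage,
    ckd_pooled = p$ckd_stage != "none" || p$ckd_code_only,
    rrt = p$ckd_stage == "RRT",
    rrt_modality = if (p$ckd_stage == "RRT") p$rrt_modality else "none",
    t2dm = p$t2dm, hypertension = p$hypertension, cvd = p$cvd,
    at_risk = p$t2dm || p$hypertension || p$ckd_stage != "none" || p$ckd_code_only)

  list(
    demographics = tibble::tibble(
      patient_id = id, sex = p$sex,
      birth_date = as_of - round(p$age_years * 365.25)),
    labs = labs, observations = observations,
    codes = dplyr::bind_rows(codes), medications = dplyr::bind_rows(meds),
    procedures = dplyr::bind_rows(procs), truth = truth)
}

#' Generate one synthetic patient record
#'
#' Builds a longitudinal [ehr_cohort()] of one patient from a
#' [synthetic_profile()]: encounter dates follow a Poisson process at
#' `visit_rate` per year over the follow-up (plus an intake and a
#' review-date encounter), creatinine is back-solved from the target eGFR
#' trajectory via the inverse CKD-EPI relation, uACR is lognormal around its
#' central level, and HbA1c, blood pressure, codes, medications and
#' procedures are emitted according to the target phenotypes. At zero noise
#' and perfect coding the record satisfies its target phenotype definitions
#' exactly.
#'
#' @param profile a [synthetic_profile()].
#' @param as_of review date anchoring the record (default `"2021-02-07"`).
#' @param seed optional integer seed.
#' @return list with `cohort` (a one-patient `ehr_cohort`) and `truth` (a
#'   one-row ground-truth tibble).
#' @export
generate_patient <- function(profile, as_of = "2021-02-07", seed = NULL) {
  stopifnot(inherits(profile, "synthetic_profile"))
  if (!is.null(seed)) set.seed(seed)
  ent <- .generate_entities(profile, as_of)
  list(cohort = ehr_cohort(demographics = ent$demographics, labs = ent$labs,
                           observations = ent$observations, codes = ent$codes,
                           medications = ent$medications,
                           procedures = ent$procedures),
       truth = ent$truth)
}

# profile constructors for the six validation subgroups
.subgroup_profile <- function(subgroup, i, noise) {
  id <- sprintf("S%d_%03d", subgroup, i)
  sex <- if (i %% 2 == 0) "male" else "female"
  age <- 30 + (i * 7) %% 46          # 30..75
  base <- list(patient_id = id, sex = sex, age_years = age,
               followup_years = 4 + (i %% 8), visit_rate = 4,
               creatinine_cv = noise$creatinine_cv,
               uacr_sigma = noise$uacr_sigma,
               coding_sensitivity = noise$coding_sensitivity,
               coding_specificity = noise$coding_specificity)
  extra <- switch(as.character(subgroup),
    "1" = if (i %% 2 == 0) list(t2dm = TRUE) else list(hypertension = TRUE),
    "2" = list(ckd_stage = c("CKD1", "CKD2", "CKD3a")[(i %% 3) + 1]),
    "3" = list(ckd_stage = c("CKD3b", "CKD4")[(i %% 2) + 1]),
    "4" = if (i %% 2 == 0) {
      list(ckd_stage = "RRT",
           rrt_modality = c("haemodialysis", "transplant",
                            "peritoneal_dialysis")[(i %% 3) + 1])
    } else list(ckd_stage = "CKD5"),
    "5" = list(ckd_code_only = TRUE, t2dm = TRUE, hypertension = TRUE,
               cvd = TRUE),
    "6" = list(ckd_code_only = TRUE, t2dm = TRUE, hypertension = TRUE,
               t2dm_channels = "medications",
               hypertension_channels = "medications"))
  do.call(synthetic_profile, c(base, extra))
}

#' Generate a stratified synthetic validation cohort
#'
#' Draws patient profiles so that [subgroup_assign()] reproduces the
#' requested subgroup sizes, with the default census
#' `c(50, 49, 51, 50, 45, 43)` (total 288): subgroup 1 are at-risk patients
#' without CKD; 2-4 span mild to end-stage CKD and RRT; 5 carries two or
#' more coded comorbidities with code-only CKD; 6 carries three or more
#' chronic-disease medications. Generation is noise-free by default
#' (zero laboratory noise, perfect coding), so classifier output equals the
#' ground truth by construction; pass non-zero noise levels to study
#' degradation.
#'
#' @param n_per_subgroup integer vector of six subgroup sizes.
#' @param seed integer RNG seed; the same seed reproduces the cohort
#'   byte-for-byte.
#' @param as_of review date (default `"2021-02-07"`).
#' @param creatinine_cv,uacr_sigma,coding_sensitivity,coding_specificity
#'   noise levels applied to every profile.
#' @return list with `cohort` (an [ehr_cohort()]), `truth` (ground-truth
#'   tibble with intended `subgroup`), and `profiles`.
#' @export
generate_validation_cohort <- function(n_per_subgroup = c(50, 49, 51, 50, 45, 43),
                                       seed = 1L, as_of = "2021-02-07",
                                       creatinine_cv = 0, uacr_sigma = 0,
                                       coding_sensitivity = 1,
                                       coding_specificity = 1) {
  stopifnot(length(n_per_subgroup) == 6L, all(n_per_subgroup >= 0))
  set.seed(seed)
  noise <- list(creatinine_cv = creatinine_cv, uacr_sigma = uacr_sigma,
                coding_sensitivity = coding_sensitivity,
                coding_specificity = coding_specificity)
  profiles <- purrr::flatten(purrr::map(1:6, function(sg) {
    purrr::map(seq_len(n_per_subgroup[sg]), ~ .subgroup_profile(sg, .x, noise))
  }))
  if (length(profiles) == 0L) {
    return(list(cohort = ehr_cohort(.empty_entity("demographics")),
                truth = tibble::tibble(), profiles = list()))
  }
  parts <- purrr::map(profiles, .generate_entities, as_of = as_of)
  entity <- function(nm) dplyr::bind_rows(purrr::map(parts, nm))
  truth <- entity("truth")
  truth$subgroup <- factor(rep(as.character(1:6), n_per_subgroup),
                           levels = c(as.character(1:6), "ineligible"))
  cohort <- ehr_cohort(demographics = entity("demographics"),
                       labs = entity("labs"),
                       observations = entity("observations"),
                       codes = entity("codes"),
                       medications = entity("medications"),
                       procedures = entity("procedures"))
  list(cohort = cohort, truth = truth, profiles = profiles)
}

#' Randomly thin a cohort's entries
#'
#' Uniform fixed-count subsampling per entity type (exactly
#' `round(n * drop_fraction)` entries removed, a hypergeometric rather than
#' Bernoulli design so counts are exact); ground truth is untouched. Used to
#' study completeness metrics and classifier degradation under data loss.
#'
#' @param cohort an [ehr_cohort()].
#' @param drop_fraction named numeric vector in `[0, 1]` with any of
#'   `labs`, `observations`, `codes`, `medications`, `procedures`.
#' @param seed integer seed.
#' @return the thinned `ehr_cohort`.
#' @export
degrade <- function(cohort, drop_fraction = c(labs = 0), seed = 1L) {
  stopifnot(inherits(cohort, "ehr_cohort"),
            all(drop_fraction >= 0), all(drop_fraction <= 1))
  bad <- setdiff(names(drop_fraction), setdiff(.entity_names, "demographics"))
  if (length(bad)) stop("unknown entity type(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  set.seed(seed)
  out <- cohort
  for (nm in names(drop_fraction)) {
    tbl <- out[[nm]]
    n_drop <- round(nrow(tbl) * drop_fraction[[nm]])
    if (n_drop > 0) {
      keep <- sort(sample.int(nrow(tbl), nrow(tbl) - n_drop))
      out[[nm]] <- tbl[keep, , drop = FALSE]
    }
  }
  structure(out, class = "ehr_cohort")
}
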