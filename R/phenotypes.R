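.ckd_stage_levels <- c("none", "CKD1", "CKD2", "CKD3a", "CKD3b", "CKD4", "CKD5", "RRT")
.stage_from_index <- c("CKD1", "CKD2", "CKD3a", "CKD4", "CKD5")

.basis <- function(x) paste(x, collapse = ";")

#' Algorithm configuration for the CKD classifier
#'
#' Bundles the CKD definition variant, the review date, and the underlying
#' threshold/code-set configuration.
#'
#' Variants (the sensitivity-analysis definitions):
#' \describe{
#'   \item{`stage1_plus`}{default — CKD of any stage, i.e. persistent eGFR
#'     reduction, persistent albuminuria with preserved eGFR (stages 1-2), or
#'     RRT.}
#'   \item{`stage3a_plus`}{eGFR-defined CKD only (the albuminuria-only branch
#'     for stages 1-2 is disabled).}
#'   \item{`stringent_uacr`}{as the default, but the albuminuria rule for
#'     stages 1-2 additionally requires two elevated readings >= 90 days
#'     apart.}
#' }
#'
#' @param variant one of `"stage1_plus"`, `"stage3a_plus"`, `"stringent_uacr"`.
#' @param as_of review date; `NULL` means the latest entry date in the cohort
#'   being classified.
#' @param config a [load_config()] object.
#' @return an `algorithm_config` object.
#' @export
algorithm_config <- function(variant = c("stage1_plus", "stage3a_plus", "stringent_uacr"),
                             as_of = NULL, config = load_config()) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "phen_config"))
  if (!is.null(as_of)) as_of <- as.Date(as_of)
  structure(list(variant = variant, as_of = as_of, config = config),
            class = "algorithm_config")
}

# Latest entry date across all entities (fallback review date).
.cohort_as_of <- function(cohort) {
  dates <- unlist(purrr::map(cohort[setdiff(.entity_names, "demographics")],
                             ~ as.numeric(.x$date)))
  if (length(dates) == 0L) Sys.Date() else as.Date(max(dates), origin = "1970-01-01")
}

.resolve_acfg <- function(cohort, config) {
  if (inherits(config, "phen_config")) config <- algorithm_config(config = config)
  stopifnot(inherits(config, "algorithm_config"))
  if (is.null(config$as_of)) config$as_of <- .cohort_as_of(cohort)
  config
}

.upto <- function(tbl, as_of) tbl[tbl$date <= as_of, , drop = FALSE]

# ---------------------------------------------------------------------------
# per-record workers

.rrt_rec <- function(rec, cfg, as_of) {
  th <- cfg$thresholds
  codes <- .upto(rec$codes, as_of)
  procs <- .upto(rec$procedures, as_of)
  all_codes <- c(codes$code, procs$code)
  all_systems <- c(codes$system, procs$system)
  all_dates <- c(codes$date, procs$date)
  if (length(all_codes) == 0L) {
    return(list(rrt = FALSE, modality = "none"))
  }
  transplant <- match_code(all_codes, all_systems, "rrt_transplant", cfg)
  dialysis <- match_code(all_codes, all_systems, "rrt_dialysis", cfg)
  if (!any(transplant) && !any(dialysis)) {
    return(list(rrt = FALSE, modality = "none"))
  }
  if (any(transplant)) {
    return(list(rrt = TRUE, modality = "transplant"))
  }
  # maintenance-dialysis (episodic-dialysis guard): a dialysis-modality label
  # requires enough recent dialysis-coded events; older isolated events still
  # flag RRT but with unspecified modality.
  window_start <- as_of - th$dialysis_maintenance_window_days
  recent <- dialysis & all_dates >= window_start & all_dates <= as_of
  if (sum(recent) >= th$dialysis_maintenance_count) {
    haemo <- match_code(all_codes[recent], all_systems[recent], "rrt_haemodialysis", cfg)
    perit <- match_code(all_codes[recent], all_systems[recent], "rrt_peritoneal_dialysis", cfg)
    modality <- if (any(haemo)) "haemodialysis"
                else if (any(perit)) "peritoneal_dialysis" else "unspecified"
    return(list(rrt = TRUE, modality = modality))
  }
  list(rrt = TRUE, modality = "unspecified")
}

.ckd_rec <- function(rec, acfg) {
  cfg <- acfg$config; th <- cfg$thresholds; as_of <- acfg$as_of
  series <- egfr_series_record(rec, cfg$ckd_epi)
  series <- series[series$date <= as_of, , drop = FALSE]
  latest_egfr <- if (nrow(series)) series$egfr[nrow(series)] else NA_real_
  uacr <- .upto(rec$labs[rec$labs$analyte == "uacr", , drop = FALSE], as_of)
  latest_uacr <- if (nrow(uacr)) uacr$value[nrow(uacr)] else NA_real_
  g <- if (!is.na(latest_egfr)) as.character(g_stage(latest_egfr, th$g_stage_boundaries)) else NA_character_
  a <- if (!is.na(latest_uacr)) as.character(a_stage(latest_uacr, th$a_stage_boundaries)) else NA_character_

  stage <- "none"; basis <- character(); pooled <- FALSE

  rrt <- .rrt_rec(rec, cfg, as_of)
  if (rrt$rrt) {
    stage <- "RRT"; basis <- "rrt_codes"; pooled <- TRUE
  } else {
    chron <- persistent_low_egfr(series, th$egfr_low_threshold,
                                 th$egfr_persistence_days, as_of,
                                 th$require_latest_low)
    if (chron$satisfied) {
      staging_value <- if (identical(th$staging_aggregate, "median")) {
        stats::median(series$egfr)
      } else latest_egfr
      gs <- as.character(g_stage(staging_value, th$g_stage_boundaries))
      # chronicity established: the label is at worst 3a even if the staging
      # aggregate drifts above the threshold (possible with the guard off)
      stage <- switch(gs, G1 = "CKD3a", G2 = "CKD3a", G3a = "CKD3a",
                      G3b = "CKD3b", G4 = "CKD4", G5 = "CKD5")
      basis <- "egfr_criteria"; pooled <- TRUE
    } else if (acfg$variant != "stage3a_plus") {
      span <- if (acfg$variant == "stringent_uacr") th$uacr_stringent_span_days else th$uacr_min_span_days
      alb <- persistent_albuminuria(
        tibble::tibble(date = uacr$date, value = uacr$value),
        th$uacr_elevated, th$uacr_min_count, span, as_of)
      if (alb$satisfied && (is.na(latest_egfr) || latest_egfr >= th$egfr_low_threshold)) {
        stage <- if (is.na(latest_egfr) || latest_egfr >= th$g_stage_boundaries[1]) "CKD1" else "CKD2"
        basis <- "uacr_criteria"; pooled <- TRUE
      }
    }
    if (stage == "none") {
      codes <- .upto(rec$codes, as_of)
      renal <- match_code(codes$code, codes$system, "ckd_related", cfg)
      if (any(renal)) {
        pooled <- TRUE
        basis <- c(basis, "ckd_related_codes")
        implied <- code_implied_stage(codes$code[renal], codes$system[renal], cfg)
        if (any(!is.na(implied))) {
          # latest stage-implying code wins; ties broken towards the more
          # severe stage
          ok <- which(!is.na(implied))
          dts <- codes$date[renal][ok]
          pick <- ok[dts == max(dts)]
          stage <- .stage_from_index[max(implied[pick])]
          basis <- c(basis, "code_implied_stage")
        }
      }
    }
  }
  rrt_flag <- rrt[["rrt"]]; rrt_modality <- rrt[["modality"]]
  tibble::tibble(patient_id = rec$patient_id, pooled_positive = pooled,
                 stage = stage, g_stage = g, a_stage = a,
                 rrt = rrt_flag, rrt_modality = rrt_modality,
                 basis = .basis(basis))
}

.t2dm_rec <- function(rec, cfg, as_of) {
  th <- cfg$thresholds
  hba1c <- .upto(rec$labs[rec$labs$analyte == "hba1c", , drop = FALSE], as_of)
  meds <- .upto(rec$medications, as_of)
  codes <- .upto(rec$codes, as_of)
  basis <- character()
  if (sum(hba1c$value >= th$hba1c_elevated) >= th$hba1c_min_count) basis <- c(basis, "labs")
  if (nrow(meds) && any(match_code(meds$atc_code, "ATC", "glucose_lowering_med", cfg))) {
    basis <- c(basis, "medications")
  }
  if (nrow(codes) && any(match_code(codes$code, codes$system, "t2dm", cfg))) {
    basis <- c(basis, "codes")
  }
  list(positive = length(basis) > 0L, basis = .basis(basis))
}

.htn_rec <- function(rec, cfg, as_of) {
  th <- cfg$thresholds
  codes <- .upto(rec$codes, as_of)
  meds <- .upto(rec$medications, as_of)
  obs <- .upto(rec$observations, as_of)
  basis <- character()
  if (nrow(codes) && any(match_code(codes$code, codes$system, "hypertension", cfg))) {
    basis <- c(basis, "codes")
  }
  if (nrow(meds) && any(match_code(meds$atc_code, "ATC", "antihypertensive_med", cfg))) {
    basis <- c(basis, "medications")
  }
  elevated <- (obs$kind == "systolic_bp" & obs$value >= th$bp_systolic) |
    (obs$kind == "diastolic_bp" & obs$value >= th$bp_diastolic)
  if (length(unique(obs$date[elevated])) >= th$bp_min_count) {
    basis <- c(basis, "observations")
  }
  list(positive = length(basis) > 0L, basis = .basis(basis))
}

.cvd_rec <- function(rec, cfg, as_of) {
  codes <- .upto(rec$codes, as_of)
  pos <- nrow(codes) > 0L && any(match_code(codes$code, codes$system, "cvd", cfg))
  list(positive = pos, basis = if (pos) "codes" else "")
}

.at_risk_rec <- function(rec, cfg, as_of, t2dm_pos, htn_pos, external_cvd_risk = NA_real_) {
  if (t2dm_pos || htn_pos) return(TRUE)
  codes <- .upto(rec$codes, as_of)
  if (nrow(codes) && any(match_code(codes$code, codes$system, "ckd_related", cfg) |
                         match_code(codes$code, codes$system, "aki", cfg))) {
    return(TRUE)
  }
  !is.na(external_cvd_risk) && external_cvd_risk > cfg$thresholds$cvd_risk_cutoff
}

# ---------------------------------------------------------------------------
# cohort-level classifiers (tibble in, tibble out)

#' Classify renal replacement therapy and modality
#'
#' A patient is RRT-positive when any diagnosis or procedure code matches an
#' RRT concept. Transplant codes dominate dialysis codes for the modality. A
#' maintenance-dialysis modality label (haemodialysis / peritoneal dialysis)
#' additionally requires at least 3 dialysis-coded events in the 90 days
#' before the review date — the episodic-dialysis guard: a patient with only
#' historic dialysis episodes is still RRT-positive but with modality
#' `"unspecified"`. Both the event count and the window are configurable.
#'
#' @param cohort an [ehr_cohort()].
#' @param config an [algorithm_config()] (or a bare [load_config()] object,
#'   classified at the cohort's latest entry date).
#' @return tibble with `patient_id`, `rrt` (logical), `rrt_modality`.
#' @export
classify_rrt <- function(cohort, config = load_config()) {
  acfg <- .resolve_acfg(cohort, config)
  purrr::map_dfr(split_records(cohort), function(rec) {
    r <- .rrt_rec(rec, acfg$config, acfg$as_of)
    tibble::tibble(patient_id = rec$patient_id, rrt = r$rrt, rrt_modality = r$modality)
  })
}

#' Classify CKD status and stage
#'
#' The pooled CKD phenotype and stage, evaluated in priority order:
#' \enumerate{
#'   \item RRT (per [classify_rrt()]) — mutually exclusive with all numeric
#'     stages, labelled `"RRT"`;
#'   \item laboratory staging — persistent eGFR reduction
#'     ([persistent_low_egfr()]) stages to CKD3a-CKD5 from the most recent
#'     eGFR; otherwise persistent albuminuria ([persistent_albuminuria()])
#'     with preserved eGFR stages to CKD1 (eGFR >= 90 or no eGFR on record)
#'     or CKD2 (eGFR 60-89);
#'   \item code-only — any CKD-related diagnosis code makes the patient
#'     pooled-positive; a stage-implying code (e.g. an N18.3-equivalent)
#'     supplies a stage when laboratory staging was impossible.
#' }
#' Under the `stage3a_plus` variant the albuminuria-only branch is disabled;
#' under `stringent_uacr` the albuminuria rule for the CKD1/CKD2 branch
#' requires two elevated readings >= 90 days apart.
#'
#' @inheritParams classify_rrt
#' @return tibble with one row per patient: `patient_id`, `pooled_positive`,
#'   `stage` (factor over none/CKD1-5/RRT), `g_stage`, `a_stage`, `rrt`,
#'   `rrt_modality`, and `basis` (semicolon-joined evidence set drawn from
#'   `egfr_criteria`, `uacr_criteria`, `rrt_codes`, `ckd_related_codes`,
#'   `code_implied_stage`).
#' @export
classify_ckd <- function(cohort, config = algorithm_config()) {
  acfg <- .resolve_acfg(cohort, config)
  out <- purrr::map_dfr(split_records(cohort), .ckd_rec, acfg = acfg)
  out$stage <- factor(out$stage, levels = .ckd_stage_levels)
  out
}

#' Classify type 2 diabetes
#'
#' Positive on any arm of: two or more HbA1c results at or above 48 mmol/mol;
#' any glucose-lowering medication (ATC A10); any diabetes diagnosis code.
#' A single historic elevated HbA1c among normal results, with no other
#' evidence, is classified as no diabetes.
#'
#' @inheritParams classify_rrt
#' @return tibble with `patient_id`, `positive`, `basis` (subset of
#'   `labs`/`medications`/`codes`, semicolon-joined).
#' @export
classify_t2dm <- function(cohort, config = load_config()) {
  acfg <- .resolve_acfg(cohort, config)
  purrr::map_dfr(split_records(cohort), function(rec) {
    r <- .t2dm_rec(rec, acfg$config, acfg$as_of)
    tibble::tibble(patient_id = rec$patient_id, positive = r$positive, basis = r$basis)
  })
}

#' Classify hypertension
#'
#' Positive on any arm of: any hypertension diagnosis code; any
#' antihypertensive medication (ATC C02/C03/C07/C08/C09); or elevated clinic
#' blood pressure (systolic >= 140 or diastolic >= 90 mmHg) on two or more
#' distinct dates. Thresholds and the reading count are configurable.
#'
#' @inheritParams classify_rrt
#' @return tibble with `patient_id`, `positive`, `basis` (subset of
#'   `codes`/`medications`/`observations`).
#' @export
classify_hypertension <- function(cohort, config = load_config()) {
  acfg <- .resolve_acfg(cohort, config)
  purrr::map_dfr(split_records(cohort), function(rec) {
    r <- .htn_rec(rec, acfg$config, acfg$as_of)
    tibble::tibble(patient_id = rec$patient_id, positive = r$positive, basis = r$basis)
  })
}

#' Classify cardiovascular disease
#'
#' Code-only phenotype: positive iff any diagnosis code matches the
#' cardiovascular concept (ischaemic heart disease and cerebrovascular
#' chapters by default). Medications and observations are deliberately not
#' used.
#'
#' @inheritParams classify_rrt
#' @return tibble with `patient_id`, `positive`, `basis`.
#' @export
classify_cvd <- function(cohort, config = load_config()) {
  acfg <- .resolve_acfg(cohort, config)
  purrr::map_dfr(split_records(cohort), function(rec) {
    r <- .cvd_rec(rec, acfg$config, acfg$as_of)
    tibble::tibble(patient_id = rec$patient_id, positive = r$positive, basis = r$basis)
  })
}

#' Flag patients at risk of CKD
#'
#' At-risk is defined as: diabetes-positive, or hypertension-positive, or any
#' renal/acute-kidney-injury diagnosis code, or an externally supplied
#' five-year cardiovascular risk score strictly greater than 15 percent. The
#' risk score is accepted as an input, not computed.
#'
#' @inheritParams classify_rrt
#' @param external_cvd_risk optional named numeric vector (percent), keyed by
#'   patient id.
#' @return tibble with `patient_id`, `at_risk`.
#' @export
at_risk_ckd <- function(cohort, config = load_config(), external_cvd_risk = NULL) {
  acfg <- .resolve_acfg(cohort, config)
  purrr::map_dfr(split_records(cohort), function(rec) {
    t2 <- .t2dm_rec(rec, acfg$config, acfg$as_of)
    ht <- .htn_rec(rec, acfg$config, acfg$as_of)
    risk <- if (!is.null(external_cvd_risk) && rec$patient_id %in% names(external_cvd_risk)) {
      external_cvd_risk[[rec$patient_id]]
    } else NA_real_
    tibble::tibble(patient_id = rec$patient_id,
                   at_risk = .at_risk_rec(rec, acfg$config, acfg$as_of,
                                          t2$positive, ht$positive, risk))
  })
}

#' Run every phenotype classifier over a cohort
#'
#' Single-pass convenience wrapper producing the full label table: pooled
#' CKD and stage, RRT and modality, diabetes, hypertension, cardiovascular
#' disease and the at-risk flag, with the evidence basis for each.
#'
#' @inheritParams classify_rrt
#' @param external_cvd_risk optional named numeric vector (percent) for the
#'   at-risk flag.
#' @return tibble with one row per patient and columns `patient_id`,
#'   `ckd_pooled`, `ckd_stage`, `g_stage`, `a_stage`, `rrt`, `rrt_modality`,
#'   `t2dm`, `hypertension`, `cvd`, `at_risk`, plus `ckd_basis`,
#'   `t2dm_basis`, `hypertension_basis`, `cvd_basis`.
#' @export
#' @examples
#' cohort <- generate_validation_cohort(n_per_subgroup = c(2, 2, 2, 2, 2, 2),
#'                                      seed = 1)$cohort
#' classify_cohort(cohort)
classify_cohort <- function(cohort, config = algorithm_config(),
                            external_cvd_risk = NULL) {
  acfg <- .resolve_acfg(cohort, config)
  recs <- split_records(cohort)
  out <- purrr::map_dfr(recs, function(rec) {
    ckd <- .ckd_rec(rec, acfg)
    t2 <- .t2dm_rec(rec, acfg$config, acfg$as_of)
    ht <- .htn_rec(rec, acfg$config, acfg$as_of)
    cv <- .cvd_rec(rec, acfg$config, acfg$as_of)
    risk <- if (!is.null(external_cvd_risk) && rec$patient_id %in% names(external_cvd_risk)) {
      external_cvd_risk[[rec$patient_id]]
    } else NA_real_
    tibble::tibble(
      patient_id = rec$patient_id,
      ckd_pooled = ckd$pooled_positive, ckd_stage = ckd$stage,
      g_stage = ckd$g_stage, a_stage = ckd$a_stage,
      rrt = ckd$rrt, rrt_modality = ckd$rrt_modality,
      t2dm = t2$positive, hypertension = ht$positive, cvd = cv$positive,
      at_risk = .at_risk_rec(rec, acfg$config, acfg$as_of, t2$positive,
                             ht$positive, risk),
      ckd_basis = ckd$basis, t2dm_basis = t2$basis,
      hypertension_basis = ht$basis, cvd_basis = cv$basis)
  })
  out$ckd_stage <- factor(out$ckd_stage, levels = .ckd_stage_levels)
  out
}
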