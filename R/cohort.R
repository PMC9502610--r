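#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

.lab_analytes <- c("serum_creatinine", "egfr_reported", "uacr", "hba1c", "other")
.canonical_units <- c(serum_creatinine = "umol/L", egfr_reported = "mL/min/1.73m2",
                      uacr = "mg/mmol", hba1c = "mmol/mol")
.obs_kinds <- c("systolic_bp", "diastolic_bp", "other")
.entity_names <- c("demographics", "labs", "observations", "codes",
                   "medications", "procedures")

.empty_entity <- function(which) {
  switch(which,
    demographics = tibble::tibble(patient_id = character(), sex = character(),
                                  birth_date = as.Date(character())),
    labs = tibble::tibble(patient_id = character(), analyte = character(),
                          value = double(), units = character(),
                          date = as.Date(character()), censor = character()),
    observations = tibble::tibble(patient_id = character(), kind = character(),
                                  value = double(), date = as.Date(character())),
    codes = tibble::tibble(patient_id = character(), system = character(),
                           code = character(), date = as.Date(character()),
                           setting = character()),
    medications = tibble::tibble(patient_id = character(), atc_code = character(),
                                 date = as.Date(character())),
    procedures = tibble::tibble(patient_id = character(), system = character(),
                                code = character(), date = as.Date(character()))
  )
}

.code_pattern_ok <- function(system, code) {
  norm <- normalise_code(code)
  ok <- rep(TRUE, length(norm))
  icd <- system %in% "ICD10AM"
  icpc <- system %in% "ICPC2"
  ok[icd] <- grepl("^[A-Z][0-9]+$", norm[icd])
  # ICPC-2 rubric: letter + 2 digits, optional PLUS-style extension digits
  ok[icpc] <- grepl("^[A-Z][0-9]{2}[0-9]*$", norm[icpc])
  ok & nzchar(norm)
}

.atc_pattern_ok <- function(code) {
  grepl("^[A-Z][0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?$", normalise_code(code))
}

#' Construct a linked EHR cohort
#'
#' An `ehr_cohort` is the package's container for linked longitudinal EHR
#' data: one tibble per entity (demographics, laboratory results,
#' observations, coded diagnoses, medications, procedures), all keyed by
#' `patient_id`, each date-sorted within patient (stable, so same-day entries
#' keep their input order). The constructor is strict: any invariant
#' violation is an error. To ingest possibly dirty flat files with
#' drop-and-count semantics use [load_cohort()].
#'
#' Invariants enforced: unique non-empty `patient_id`s in demographics; every
#' entry belongs to a known patient and is dated strictly after that
#' patient's birth date; laboratory values are non-negative and carried in
#' canonical units (creatinine umol/L, uACR mg/mmol, HbA1c mmol/mol, eGFR
#' mL/min/1.73m2); the `above_limit` censor flag is only legal for reported
#' eGFR; blood pressures lie in physiological ranges; diagnosis, ATC and
#' procedure codes match their systems' formats.
#'
#' @param demographics tibble with `patient_id`, `sex` (`"male"`/`"female"`),
#'   `birth_date` (`Date`).
#' @param labs,observations,codes,medications,procedures optional entity
#'   tibbles; see the shipped CSV schema in [load_cohort()].
#' @return an `ehr_cohort` object (a named list of tibbles).
#' @export
ehr_cohort <- function(demographics, labs = NULL, observations = NULL,
                       codes = NULL, medications = NULL, procedures = NULL) {
  entities <- list(demographics = demographics, labs = labs,
                   observations = observations, codes = codes,
                   medications = medications, procedures = procedures)
  entities <- purrr::imap(entities, function(tbl, nm) {
    if (is.null(tbl) || nrow(tbl) == 0L) return(.empty_entity(nm))
    tibble::as_tibble(tbl)
  })
  d <- entities$demographics
  if (!all(c("patient_id", "sex", "birth_date") %in% names(d))) {
    stop("demographics must have patient_id, sex, birth_date", call. = FALSE)
  }
  d$patient_id <- as.character(d$patient_id)
  d$birth_date <- as.Date(d$birth_date)
  if (any(!nzchar(d$patient_id)) || anyNA(d$patient_id)) {
    stop("patient_id must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(d$patient_id)) {
    stop("duplicate patient_id in demographics", call. = FALSE)
  }
  if (!all(d$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  birth <- stats::setNames(d$birth_date, d$patient_id)
  check_common <- function(tbl, what) {
    if (nrow(tbl) == 0L) return(tbl)
    tbl$patient_id <- as.character(tbl$patient_id)
    tbl$date <- as.Date(tbl$date)
    if (anyNA(tbl$date)) stop(what, ": unparseable dates", call. = FALSE)
    unknown <- setdiff(tbl$patient_id, d$patient_id)
    if (length(unknown)) {
      stop(what, ": entries for unknown patient(s) ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    }
    if (any(tbl$date <= birth[tbl$patient_id])) {
      stop(what, ": entries dated on or before birth_date", call. = FALSE)
    }
    tbl[order(tbl$patient_id, tbl$date), , drop = FALSE]
  }
  l <- entities$labs
  if (nrow(l)) {
    if (!"censor" %in% names(l)) l$censor <- "none"
    if (!"units" %in% names(l)) l$units <- unname(.canonical_units[l$analyte])
    l$censor[is.na(l$censor)] <- "none"
    if (!all(l$analyte %in% .lab_analytes)) stop("unknown lab analyte", call. = FALSE)
    if (any(is.na(l$value) | l$value < 0)) stop("lab values must be >= 0", call. = FALSE)
    canon <- l$analyte != "other"
    if (any(l$units[canon] != .canonical_units[l$analyte[canon]])) {
      stop("labs must carry canonical units (convert at ingest)", call. = FALSE)
    }
    if (!all(l$censor %in% c("none", "above_limit", "below_limit"))) {
      stop("bad censor value", call. = FALSE)
    }
    if (any(l$censor == "above_limit" & l$analyte != "egfr_reported")) {
      stop("above_limit censoring is only legal for reported eGFR", call. = FALSE)
    }
  }
  o <- entities$observations
  if (nrow(o)) {
    if (!all(o$kind %in% .obs_kinds)) stop("unknown observation kind", call. = FALSE)
    sys <- o$kind == "systolic_bp"; dia <- o$kind == "diastolic_bp"
    if (any(o$value[sys] <= 0 | o$value[sys] >= 350) ||
        any(o$value[dia] <= 0 | o$value[dia] >= 250)) {
      stop("blood pressure out of physiological range", call. = FALSE)
    }
  }
  cc <- entities$codes
  if (nrow(cc)) {
    if (!all(cc$system %in% c("ICD10AM", "ICPC2"))) stop("bad code system", call. = FALSE)
    if (!"setting" %in% names(cc)) cc$setting <- ifelse(cc$system == "ICD10AM",
                                                        "hospital", "primary_care")
    if (!all(cc$setting %in% c("hospital", "primary_care"))) {
      stop("bad care setting", call. = FALSE)
    }
    if (!all(.code_pattern_ok(cc$system, cc$code))) {
      stop("malformed diagnosis code(s)", call. = FALSE)
    }
  }
  m <- entities$medications
  if (nrow(m) && !all(.atc_pattern_ok(m$atc_code))) {
    stop("malformed ATC code(s)", call. = FALSE)
  }
  p <- entities$procedures
  if (nrow(p)) {
    if (!all(p$system %in% c("ICD10AM_procedure", "MBS"))) {
      stop("bad procedure code system", call. = FALSE)
    }
    if (any(!nzchar(trimws(p$code)))) stop("empty procedure code", call. = FALSE)
  }
  out <- list(
    demographics = d[order(d$patient_id), , drop = FALSE],
    labs = check_common(l, "labs"),
    observations = check_common(o, "observations"),
    codes = check_common(cc, "codes"),
    medications = check_common(m, "medications"),
    procedures = check_common(p, "procedures")
  )
  structure(out, class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat("<ehr_cohort> ", nrow(x$demographics), " patients\n", sep = "")
  for (nm in setdiff(.entity_names, "demographics")) {
    cat(sprintf("  %-13s %d entries\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' @export
#' @rdname ehr_cohort
#' @param cohort an `ehr_cohort`.
patient_ids <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  cohort$demographics$patient_id
}

#' Subset a cohort to a set of patients
#'
#' @param cohort an [ehr_cohort()].
#' @param ids character vector of patient ids to keep.
#' @return an `ehr_cohort` containing only those patients (ingest report, if
#'   any, is not carried over).
#' @export
cohort_subset <- function(cohort, ids) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  missing_ids <- setdiff(ids, patient_ids(cohort))
  if (length(missing_ids)) {
    stop("unknown patient ids: ", paste(utils::head(missing_ids, 3), collapse = ", "),
         call. = FALSE)
  }
  out <- purrr::map(cohort, ~ .x[.x$patient_id %in% ids, , drop = FALSE])
  structure(out, class = "ehr_cohort")
}

# One patient's slice as a plain list of tibbles (the per-record view the
# classifiers consume). Demographics become scalar fields.
patient_record <- function(cohort, id) {
  d <- cohort$demographics[cohort$demographics$patient_id == id, , drop = FALSE]
  if (nrow(d) != 1L) stop("unknown patient id: ", id, call. = FALSE)
  rec <- purrr::map(cohort[setdiff(.entity_names, "demographics")],
                    ~ .x[.x$patient_id == id, , drop = FALSE])
  rec$patient_id <- id
  rec$sex <- d$sex
  rec$birth_date <- d$birth_date
  rec
}

# Split the whole cohort into records in one pass (avoids per-patient scans).
split_records <- function(cohort) {
  ids <- patient_ids(cohort)
  pieces <- purrr::map(cohort[setdiff(.entity_names, "demographics")], function(tbl) {
    split(tbl, factor(tbl$patient_id, levels = ids))
  })
  d <- cohort$demographics
  stats::setNames(purrr::map(seq_along(ids), function(i) {
    rec <- purrr::map(pieces, ~ .x[[i]])
    rec$patient_id <- ids[i]
    rec$sex <- d$sex[i]
    rec$birth_date <- d$birth_date[i]
    rec
  }), ids)
}

#' Ingest report of a loaded cohort
#'
#' Per-table counts of rows read, loaded, reassigned and dropped (by reason)
#' recorded by [load_cohort()]. Ingest never invents rows:
#' `rows_read = loaded + dropped` for every table.
#'
#' @param cohort a cohort returned by [load_cohort()].
#' @return the ingest report (a nested list), or `NULL` for cohorts built
#'   directly with [ehr_cohort()].
#' @export
ingest_report <- function(cohort) {
  attr(cohort, "ingest_report")
}
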