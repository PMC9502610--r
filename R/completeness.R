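.completeness_types <- c("labs", "observations", "icd_codes", "icpc_codes",
                         "medications")

# per-patient entry counts over the five completeness data types
.type_counts <- function(rec) {
  c(labs = nrow(rec$labs), observations = nrow(rec$observations),
    icd_codes = sum(rec$codes$system == "ICD10AM"),
    icpc_codes = sum(rec$codes$system == "ICPC2"),
    medications = nrow(rec$medications))
}

#' Restrict a cohort to recently active patients
#'
#' A patient is active when any entry of any type falls within the window
#' `[as_of - window_years, as_of]`.
#'
#' @param cohort an [ehr_cohort()].
#' @param as_of census date.
#' @param window_years activity window, default 2 years.
#' @return the active `ehr_cohort` subset.
#' @export
activity_filter <- function(cohort, as_of, window_years = 2) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  as_of <- as.Date(as_of)
  start <- as_of - round(window_years * 365.25)
  active <- unique(unlist(purrr::map(
    cohort[setdiff(.entity_names, "demographics")],
    ~ .x$patient_id[.x$date >= start & .x$date <= as_of])))
  cohort_subset(cohort, intersect(patient_ids(cohort), active))
}

#' Data-completeness metrics for a cohort
#'
#' The three completeness dimensions plus the nested metric ladder:
#' \describe{
#'   \item{documentation}{per data type, the proportion of patients with at
#'     least one entry (the five types are laboratory results, observations,
#'     ICD codes, ICPC codes, medications);}
#'   \item{breadth}{per patient, how many of the five types are present
#'     (0-5);}
#'   \item{density}{per patient, entries per patient-year, with the span
#'     between first and last entry floored at 1 year so single-visit
#'     patients are not divided by near-zero.}
#' }
#' The four completeness flags form a nested ladder (metric4 implies metric3
#' implies metric2 implies metric1). Defaults: metric1 — at least one entry
#' of any type; metric2 — at least one laboratory result and one coded
#' diagnosis (ICD or ICPC); metric3 — at least 3 laboratory results, one
#' coded diagnosis and one medication; metric4 — at least 3 laboratory
#' results, 3 observation entries, 1 coded diagnosis and 1 medication entry.
#'
#' @param cohort an [ehr_cohort()].
#' @param as_of optional census date; entries after it are ignored.
#' @return a `completeness_summary` object; [tidy.completeness_summary()]
#'   returns the per-patient table and [glance.completeness_summary()] the
#'   cohort-level row (documentation proportions, median/IQR breadth and
#'   density, metric proportions).
#' @export
completeness_summary <- function(cohort, as_of = NULL) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (nrow(cohort$demographics) == 0L) stop("cohort is empty", call. = FALSE)
  if (!is.null(as_of)) {
    as_of <- as.Date(as_of)
    cohort_cut <- purrr::map(cohort, function(tbl) {
      if ("date" %in% names(tbl)) tbl[tbl$date <= as_of, , drop = FALSE] else tbl
    })
    cohort <- structure(cohort_cut, class = "ehr_cohort")
  }
  recs <- split_records(cohort)
  patients <- purrr::map_dfr(recs, function(rec) {
    counts <- .type_counts(rec)
    dates <- c(rec$labs$date, rec$observations$date, rec$codes$date,
               rec$medications$date)
    span <- if (length(dates)) {
      max(1, as.numeric(max(dates) - min(dates)) / 365.25)
    } else NA_real_
    n_codes <- counts[["icd_codes"]] + counts[["icpc_codes"]]
    total <- sum(counts)
    tibble::tibble(
      patient_id = rec$patient_id,
      n_labs = counts[["labs"]], n_observations = counts[["observations"]],
      n_icd_codes = counts[["icd_codes"]], n_icpc_codes = counts[["icpc_codes"]],
      n_medications = counts[["medications"]],
      breadth = sum(counts > 0), span_years = span,
      density = if (total > 0) total / span else 0,
      lab_density = if (counts[["labs"]] > 0) counts[["labs"]] / span else 0,
      metric1 = total >= 1,
      metric2 = counts[["labs"]] >= 1 && n_codes >= 1,
      metric3 = counts[["labs"]] >= 3 && n_codes >= 1 && counts[["medications"]] >= 1,
      metric4 = counts[["labs"]] >= 3 && counts[["observations"]] >= 3 &&
        n_codes >= 1 && counts[["medications"]] >= 1)
  })
  documentation <- tibble::tibble(
    data_type = .completeness_types,
    proportion = c(mean(patients$n_labs > 0), mean(patients$n_observations > 0),
                   mean(patients$n_icd_codes > 0), mean(patients$n_icpc_codes > 0),
                   mean(patients$n_medications > 0)))
  structure(list(patients = patients, documentation = documentation,
                 as_of = as_of), class = "completeness_summary")
}

#' @export
print.completeness_summary <- function(x, ...) {
  cat("<completeness_summary> ", nrow(x$patients), " patients\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Per-patient completeness table
#' @param x a [completeness_summary()].
#' @param ... unused.
#' @return tibble, one row per patient.
#' @export
tidy.completeness_summary <- function(x, ...) x$patients

#' Cohort-level completeness summary
#' @param x a [completeness_summary()].
#' @param ... unused.
#' @return one-row tibble with documentation proportions, breadth and
#'   density medians/IQRs, and the proportion of patients meeting each
#'   metric.
#' @export
glance.completeness_summary <- function(x, ...) {
  p <- x$patients
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  bd <- q(p$breadth); dn <- q(p$density)
  doc <- stats::setNames(x$documentation$proportion,
                         paste0("documented_", x$documentation$data_type))
  dplyr::bind_cols(
    tibble::tibble(n_patients = nrow(p)),
    tibble::as_tibble(as.list(doc)),
    tibble::tibble(breadth_median = bd[2], breadth_q1 = bd[1], breadth_q3 = bd[3],
                   density_median = dn[2], density_q1 = dn[1], density_q3 = dn[3],
                   metric1 = mean(p$metric1), metric2 = mean(p$metric2),
                   metric3 = mean(p$metric3), metric4 = mean(p$metric4)))
}
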