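#' Load a cohort from flat per-entity tables
#'
#' Reads the six entity CSV/TSV files (`demographics`, `labs`,
#' `observations`, `codes`, `medications`, `procedures`), applies unit
#' conversion and invariant checks with drop-and-count semantics, and returns
#' a validated [ehr_cohort()] with an attached ingest report
#' ([ingest_report()]).
#'
#' Expected columns (ISO-8601 dates, UTF-8):
#' \describe{
#'   \item{demographics}{`patient_id`, `sex`, `birth_date`}
#'   \item{labs}{`patient_id`, `analyte`, `value`, `date`; optional `units`,
#'     `censor`. A value written `">90"`/`"<1"` is parsed as a censored
#'     reading. Creatinine reported in mg/dL is converted to umol/L
#'     (x 88.4); uACR in mg/g to mg/mmol (/ 8.84). Unknown analyte labels
#'     are routed to `analyte = "other"` and counted.}
#'   \item{observations}{`patient_id`, `kind`, `value`, `date`}
#'   \item{codes}{`patient_id`, `system`, `code`, `date`; optional `setting`}
#'   \item{medications}{`patient_id`, `atc_code`, `date`}
#'   \item{procedures}{`patient_id`, `system`, `code`, `date`}
#' }
#'
#' Rows are dropped (and counted per reason) when dates do not parse, values
#' are negative or non-numeric, units are unrecognised, codes are malformed,
#' the patient is unknown, or the entry is dated on or before the patient's
#' birth date. A missing mandatory column is a hard error naming the column.
#'
#' @param dir directory containing the entity files; alternatively supply
#'   `paths` directly.
#' @param paths optional named character vector/list of file paths keyed by
#'   entity name, overriding `dir`.
#' @return an `ehr_cohort` with attribute `ingest_report`.
#' @export
load_cohort <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    if (is.null(dir)) stop("supply `dir` or `paths`", call. = FALSE)
    paths <- file.path(dir, paste0(.entity_names, ".csv"))
    names(paths) <- .entity_names
  }
  paths <- as.list(paths)

  report <- list()
  note <- function(tbl, reason, n) {
    if (n == 0) return(invisible(NULL))
    cur <- report[[tbl]]$dropped[[reason]]
    report[[tbl]]$dropped[[reason]] <<- (if (is.null(cur)) 0L else cur) + as.integer(n)
  }

  read_entity <- function(nm, required) {
    path <- paths[[nm]]
    if (is.null(path) || !file.exists(path)) {
      if (nm == "demographics") stop("demographics table is required", call. = FALSE)
      report[[nm]] <<- list(rows_read = 0L, loaded = 0L, dropped = list())
      return(NULL)
    }
    delim <- if (grepl("\\.tsv$", path)) "\t" else ","
    tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    missing_col <- setdiff(required, names(tbl))
    if (length(missing_col)) {
      stop(nm, ": missing mandatory column(s): ",
           paste(missing_col, collapse = ", "), call. = FALSE)
    }
    report[[nm]] <<- list(rows_read = nrow(tbl), loaded = 0L, dropped = list())
    tbl
  }

  parse_date <- function(x) as.Date(x, format = "%Y-%m-%d", optional = TRUE)

  # demographics -------------------------------------------------------------
  d <- read_entity("demographics", c("patient_id", "sex", "birth_date"))
  d$birth_date <- parse_date(d$birth_date)
  d$sex <- tolower(trimws(d$sex))
  bad <- is.na(d$patient_id) | !nzchar(d$patient_id)
  note("demographics", "empty_patient_id", sum(bad)); d <- d[!bad, ]
  bad <- !d$sex %in% c("male", "female")
  note("demographics", "bad_sex", sum(bad)); d <- d[!bad, ]
  bad <- is.na(d$birth_date)
  note("demographics", "unparseable_date", sum(bad)); d <- d[!bad, ]
  bad <- duplicated(d$patient_id)
  note("demographics", "duplicate_patient_id", sum(bad)); d <- d[!bad, ]
  known <- d$patient_id
  birth <- stats::setNames(d$birth_date, d$patient_id)

  clean_common <- function(tbl, nm) {
    tbl$date <- parse_date(tbl$date)
    bad <- is.na(tbl$date)
    note(nm, "unparseable_date", sum(bad)); tbl <- tbl[!bad, ]
    bad <- !tbl$patient_id %in% known
    note(nm, "unknown_patient", sum(bad)); tbl <- tbl[!bad, ]
    bad <- tbl$date <= birth[tbl$patient_id]
    note(nm, "dated_before_birth", sum(bad)); tbl[!bad, ]
  }

  # labs ---------------------------------------------------------------------
  l <- read_entity("labs", c("patient_id", "analyte", "value", "date"))
  if (!is.null(l) && nrow(l)) {
    if (!"units" %in% names(l)) l$units <- NA_character_
    if (!"censor" %in% names(l)) l$censor <- NA_character_
    l$analyte <- tolower(trimws(l$analyte))
    unknown_analyte <- !l$analyte %in% .lab_analytes
    if (any(unknown_analyte)) {
      report$labs$reassigned_other <- sum(unknown_analyte)
      warning(sum(unknown_analyte), " lab row(s) with unknown analyte routed to 'other'",
              call. = FALSE)
      l$analyte[unknown_analyte] <- "other"
    }
    raw <- trimws(l$value)
    cens <- dplyr::case_when(startsWith(raw, ">") ~ "above_limit",
                             startsWith(raw, "<") ~ "below_limit",
                             TRUE ~ "none")
    l$censor <- dplyr::coalesce(l$censor, cens)
    l$value <- suppressWarnings(as.numeric(sub("^[<>]\\s*", "", raw)))
    bad <- is.na(l$value)
    note("labs", "nonnumeric_value", sum(bad)); l <- l[!bad, ]
    bad <- l$value < 0
    note("labs", "negative_value", sum(bad)); l <- l[!bad, ]
    # unit harmonisation
    u <- tolower(gsub("µ", "u", trimws(dplyr::coalesce(l$units, ""))))
    canonical <- c(serum_creatinine = "umol/l", egfr_reported = "ml/min/1.73m2",
                   uacr = "mg/mmol", hba1c = "mmol/mol")
    conv_cr <- l$analyte == "serum_creatinine" & u == "mg/dl"
    l$value[conv_cr] <- l$value[conv_cr] * 88.4
    conv_ua <- l$analyte == "uacr" & u == "mg/g"
    l$value[conv_ua] <- l$value[conv_ua] / 8.84
    u[conv_cr | conv_ua] <- ""
    known_u <- l$analyte == "other" | u == "" |
      u == canonical[l$analyte]
    note("labs", "unrecognised_units", sum(!known_u)); l <- l[known_u, ]
    l$units <- ifelse(l$analyte == "other", l$units,
                      .canonical_units[l$analyte])
    bad <- l$censor == "above_limit" & l$analyte != "egfr_reported"
    note("labs", "illegal_censor", sum(bad)); l <- l[!bad, ]
    l <- clean_common(l, "labs")
  }

  # observations -------------------------------------------------------------
  o <- read_entity("observations", c("patient_id", "kind", "value", "date"))
  if (!is.null(o) && nrow(o)) {
    o$kind <- tolower(trimws(o$kind))
    o$kind[!o$kind %in% .obs_kinds] <- "other"
    o$value <- suppressWarnings(as.numeric(o$value))
    bad <- is.na(o$value)
    note("observations", "nonnumeric_value", sum(bad)); o <- o[!bad, ]
    bad <- (o$kind == "systolic_bp" & (o$value <= 0 | o$value >= 350)) |
      (o$kind == "diastolic_bp" & (o$value <= 0 | o$value >= 250))
    note("observations", "out_of_range", sum(bad)); o <- o[!bad, ]
    o <- clean_common(o, "observations")
  }

  # codes --------------------------------------------------------------------
  cc <- read_entity("codes", c("patient_id", "system", "code", "date"))
  if (!is.null(cc) && nrow(cc)) {
    if (!"setting" %in% names(cc)) cc$setting <- NA_character_
    cc$system <- toupper(trimws(cc$system))
    bad <- !cc$system %in% c("ICD10AM", "ICPC2")
    note("codes", "bad_system", sum(bad)); cc <- cc[!bad, ]
    bad <- !.code_pattern_ok(cc$system, cc$code)
    note("codes", "malformed_code", sum(bad)); cc <- cc[!bad, ]
    cc$setting <- dplyr::coalesce(tolower(cc$setting),
                                  ifelse(cc$system == "ICD10AM", "hospital", "primary_care"))
    bad <- !cc$setting %in% c("hospital", "primary_care")
    note("codes", "bad_setting", sum(bad)); cc <- cc[!bad, ]
    cc <- clean_common(cc, "codes")
  }

  # medications --------------------------------------------------------------
  m <- read_entity("medications", c("patient_id", "atc_code", "date"))
  if (!is.null(m) && nrow(m)) {
    bad <- !.atc_pattern_ok(m$atc_code)
    note("medications", "malformed_code", sum(bad)); m <- m[!bad, ]
    m <- clean_common(m, "medications")
  }

  # procedures ---------------------------------------------------------------
  p <- read_entity("procedures", c("patient_id", "system", "code", "date"))
  if (!is.null(p) && nrow(p)) {
    p$system <- trimws(p$system)
    bad <- !p$system %in% c("ICD10AM_procedure", "MBS")
    note("procedures", "bad_system", sum(bad)); p <- p[!bad, ]
    bad <- !nzchar(trimws(p$code))
    note("procedures", "empty_code", sum(bad)); p <- p[!bad, ]
    p <- clean_common(p, "procedures")
  }

  cohort <- ehr_cohort(demographics = d, labs = l, observations = o,
                       codes = cc, medications = m, procedures = p)
  for (nm in names(report)) {
    dropped <- sum(unlist(report[[nm]]$dropped))
    report[[nm]]$loaded <- report[[nm]]$rows_read - as.integer(dropped)
  }
  attr(cohort, "ingest_report") <- report
  cohort
}

#' Write a cohort to flat per-entity tables
#'
#' Inverse of [load_cohort()]: writes the six entity CSVs into `dir`.
#' Re-loading the written tables reproduces the cohort (entry-set equality).
#'
#' @param cohort an [ehr_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in .entity_names) {
    readr::write_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}
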