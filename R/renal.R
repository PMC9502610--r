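.ckd_epi_2009 <- list(
  version = "2009", kappa_female = 61.9, kappa_male = 79.6,
  alpha_female = -0.329, alpha_male = -0.411, exponent_above_kappa = -1.209,
  age_factor = 0.993, female_multiplier = 1.018, scale = 141
)

#' Estimated GFR from serum creatinine (CKD-EPI)
#'
#' The 2009 CKD-EPI creatinine equation without the race term, the form in
#' which eGFR is routinely reported by Australian laboratories. Serum
#' creatinine is taken in umol/L (the sex-specific knot kappa is 61.9 umol/L
#' for females, 79.6 for males). The coefficient set is configurable so the
#' 2021 refit can be swapped in via the YAML config.
#'
#' @param sex `"male"` or `"female"` (recycled).
#' @param age_years age in years, must be >= 18 (adult equation only).
#' @param scr serum creatinine, umol/L, must be > 0.
#' @param coefficients coefficient list (defaults to the 2009 set; pass
#'   `load_config()$ckd_epi` to use a configured set).
#' @return eGFR in mL/min/1.73m2, rounded to 1 decimal place.
#' @export
#' @examples
#' ckd_epi_egfr("female", 50, 61.9)
ckd_epi_egfr <- function(sex, age_years, scr, coefficients = NULL) {
  cf <- if (is.null(coefficients)) .ckd_epi_2009 else coefficients
  n <- max(length(sex), length(age_years), length(scr))
  sex <- rep_len(sex, n); age_years <- rep_len(age_years, n); scr <- rep_len(scr, n)
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (any(is.na(scr)) || any(scr <= 0)) {
    stop("serum creatinine must be positive", call. = FALSE)
  }
  if (any(is.na(age_years)) || any(age_years < 18)) {
    stop("adult equation: age must be >= 18 years", call. = FALSE)
  }
  female <- sex == "female"
  kappa <- ifelse(female, cf$kappa_female, cf$kappa_male)
  alpha <- ifelse(female, cf$alpha_female, cf$alpha_male)
  ratio <- scr / kappa
  egfr <- cf$scale * pmin(ratio, 1)^alpha * pmax(ratio, 1)^cf$exponent_above_kappa *
    cf$age_factor^age_years * ifelse(female, cf$female_multiplier, 1)
  round(egfr, 1)
}

# Inverse of ckd_epi_egfr: creatinine (umol/L) yielding a target (unrounded)
# eGFR. Closed form: the equation is piecewise power-law in scr, continuous
# and strictly decreasing, so invert on the correct side of kappa.
ckd_epi_inverse <- function(sex, age_years, egfr_target, coefficients = NULL) {
  cf <- if (is.null(coefficients)) .ckd_epi_2009 else coefficients
  female <- sex == "female"
  kappa <- ifelse(female, cf$kappa_female, cf$kappa_male)
  alpha <- ifelse(female, cf$alpha_female, cf$alpha_male)
  base <- cf$scale * cf$age_factor^age_years * ifelse(female, cf$female_multiplier, 1)
  # eGFR at scr == kappa
  ratio <- egfr_target / base
  ifelse(ratio >= 1,
         kappa * ratio^(1 / alpha),                 # scr below the knot
         kappa * ratio^(1 / cf$exponent_above_kappa))
}

#' KDIGO G-stage from eGFR
#'
#' Half-open binning with the lower bound inclusive: G1 >= 90, G2 60-89,
#' G3a 45-59, G3b 30-44, G4 15-29, G5 < 15 (mL/min/1.73m2).
#'
#' @param egfr numeric vector of eGFR values (> 0).
#' @param boundaries decreasing stage boundaries, default `c(90, 60, 45, 30, 15)`.
#' @return factor with levels `G1` .. `G5`.
#' @export
g_stage <- function(egfr, boundaries = c(90, 60, 45, 30, 15)) {
  stopifnot(all(diff(boundaries) < 0), length(boundaries) == 5L)
  if (any(!is.na(egfr) & egfr <= 0)) stop("eGFR must be positive", call. = FALSE)
  labels <- c("G5", "G4", "G3b", "G3a", "G2", "G1")
  cut(egfr, breaks = c(0, rev(boundaries), Inf), labels = labels, right = FALSE)
}

#' KDIGO A-stage from uACR
#'
#' A1 < 3; A2 3-30 (both bounds inclusive); A3 > 30, in mg/mmol.
#'
#' @param uacr numeric vector of urine albumin-to-creatinine ratios (>= 0).
#' @param boundaries `c(lower, upper)` in mg/mmol, default `c(3, 30)`.
#' @return factor with levels `A1`, `A2`, `A3`.
#' @export
a_stage <- function(uacr, boundaries = c(3, 30)) {
  stopifnot(length(boundaries) == 2L, boundaries[1] > 0, boundaries[1] < boundaries[2])
  if (any(!is.na(uacr) & uacr < 0)) stop("uACR must be non-negative", call. = FALSE)
  out <- dplyr::case_when(
    is.na(uacr) ~ NA_character_,
    uacr < boundaries[1] ~ "A1",
    uacr <= boundaries[2] ~ "A2",
    TRUE ~ "A3"
  )
  factor(out, levels = c("A1", "A2", "A3"))
}

#' Harmonised eGFR series for every patient
#'
#' One eGFR point per serum creatinine result (computed with
#' [ckd_epi_egfr()] at the patient's age on the collection date), plus
#' laboratory-reported eGFR results on dates with no creatinine; on a
#' same-day collision the computed value takes precedence. Reported values
#' censored as "> 90" are carried at 90 with their censor flag, which
#' downstream persistence logic respects (a censored-above point never counts
#' as below a threshold).
#'
#' @param cohort an [ehr_cohort()].
#' @param config a [load_config()] object (for the CKD-EPI coefficient block).
#' @return tibble with `patient_id`, `date`, `egfr`, `source`
#'   (`"computed_ckd_epi"`/`"lab_reported"`), `censor`; date-ordered within
#'   patient.
#' @export
egfr_series <- function(cohort, config = load_config()) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  purrr::map_dfr(split_records(cohort), egfr_series_record,
                 coefficients = config$ckd_epi)
}

# Per-record worker; `rec` is a patient_record() slice.
egfr_series_record <- function(rec, coefficients = .ckd_epi_2009) {
  labs <- rec$labs
  empty <- tibble::tibble(patient_id = character(), date = as.Date(character()),
                          egfr = double(), source = character(), censor = character())
  if (is.null(labs) || nrow(labs) == 0L) return(empty)
  cr <- labs[labs$analyte == "serum_creatinine", , drop = FALSE]
  if (nrow(cr)) {
    age <- as.numeric(cr$date - rec$birth_date) / 365.25
    cr <- cr[age >= 18, , drop = FALSE]
    age <- age[age >= 18]
  }
  computed <- if (nrow(cr)) {
    tibble::tibble(patient_id = cr$patient_id, date = cr$date,
                   egfr = ckd_epi_egfr(rec$sex, age, cr$value, coefficients),
                   source = "computed_ckd_epi", censor = "none")
  } else empty
  rep_ <- labs[labs$analyte == "egfr_reported", , drop = FALSE]
  rep_ <- rep_[!rep_$date %in% computed$date, , drop = FALSE]
  reported <- if (nrow(rep_)) {
    tibble::tibble(patient_id = rep_$patient_id, date = rep_$date,
                   egfr = rep_$value, source = "lab_reported",
                   censor = rep_$censor)
  } else empty
  out <- dplyr::bind_rows(computed, reported)
  out <- out[out$egfr > 0, , drop = FALSE]
  out[order(out$date), , drop = FALSE]
}

new_chronicity_evidence <- function(satisfied, first_date = as.Date(NA),
                                    last_date = as.Date(NA),
                                    qualifying_count = 0L, span_days = NA_integer_) {
  structure(list(satisfied = satisfied, first_date = first_date,
                 last_date = last_date,
                 qualifying_count = as.integer(qualifying_count),
                 span_days = as.integer(span_days)),
            class = "chronicity_evidence")
}

#' @export
print.chronicity_evidence <- function(x, ...) {
  cat("<chronicity_evidence> satisfied:", x$satisfied,
      "| qualifying readings:", x$qualifying_count,
      "| span:", x$span_days, "days\n")
  invisible(x)
}

#' Persistently reduced eGFR (chronicity rule)
#'
#' Chronic reduction is established by two or more eGFR readings below
#' `threshold` whose dates are at least `min_span_days` apart ("3 months"
#' operationalised as >= 90 days). In addition, by default, the most recent
#' reading in the series must itself be below the threshold — the
#' resolved-AKI guard: an acute dip that has since recovered does not satisfy
#' chronicity. Points censored as above-limit never count as reduced. The
#' returned evidence reports the earliest qualifying pair.
#'
#' @param series tibble with `date` and `egfr` columns (optionally `censor`),
#'   e.g. one patient's slice of [egfr_series()].
#' @param threshold eGFR threshold, mL/min/1.73m2 (default 60).
#' @param min_span_days minimum days between the qualifying pair (default 90).
#' @param as_of only readings dated on or before `as_of` are used
#'   (`NULL` = all).
#' @param require_latest_low logical; disable to drop the resolved-AKI guard.
#' @return a `chronicity_evidence` object: `satisfied`, `first_date`,
#'   `last_date`, `qualifying_count` (readings below threshold), `span_days`.
#' @export
persistent_low_egfr <- function(series, threshold = 60, min_span_days = 90,
                                as_of = NULL, require_latest_low = TRUE) {
  if (is.null(series) || nrow(series) == 0L) return(new_chronicity_evidence(FALSE))
  if (!"censor" %in% names(series)) series$censor <- "none"
  series$date <- as.Date(series$date)
  if (!is.null(as_of)) series <- series[series$date <= as.Date(as_of), , drop = FALSE]
  if (nrow(series) == 0L) return(new_chronicity_evidence(FALSE))
  series <- series[order(series$date), , drop = FALSE]
  low <- series$egfr < threshold & series$censor != "above_limit"
  n_low <- sum(low)
  latest_low <- low[nrow(series)]
  dates <- series$date[low]
  if (n_low < 2L || (require_latest_low && !latest_low)) {
    return(new_chronicity_evidence(FALSE, qualifying_count = n_low))
  }
  # earliest qualifying pair: smallest first date, then smallest partner
  for (i in seq_len(length(dates) - 1L)) {
    j <- which(as.numeric(dates - dates[i]) >= min_span_days)
    if (length(j)) {
      j <- min(j)
      return(new_chronicity_evidence(TRUE, dates[i], dates[j], n_low,
                                     as.numeric(dates[j] - dates[i])))
    }
  }
  new_chronicity_evidence(FALSE, qualifying_count = n_low)
}

#' Persistent albuminuria
#'
#' Satisfied when at least `min_count` uACR readings reach
#' `elevated_threshold` (the KDIGO A2 boundary, 3 mg/mmol, by default) and —
#' when `min_span_days > 0`, the stringent variant — two such readings are at
#' least that many days apart. A single elevated uACR therefore never
#' establishes albuminuria under the defaults.
#'
#' @param series tibble with `date` and `value` columns (uACR, mg/mmol).
#' @param elevated_threshold elevation cut-off, mg/mmol (default 3; readings
#'   at or above it count).
#' @param min_count minimum number of elevated readings (default 2).
#' @param min_span_days 0 (default) or 90 for the stringent variant.
#' @param as_of only readings on or before `as_of` are used (`NULL` = all).
#' @return a `chronicity_evidence` object; the reported pair is the earliest
#'   elevated reading and its earliest qualifying partner.
#' @export
persistent_albuminuria <- function(series, elevated_threshold = 3, min_count = 2,
                                   min_span_days = 0, as_of = NULL) {
  if (is.null(series) || nrow(series) == 0L) return(new_chronicity_evidence(FALSE))
  series$date <- as.Date(series$date)
  if (!is.null(as_of)) series <- series[series$date <= as.Date(as_of), , drop = FALSE]
  if (nrow(series) == 0L) return(new_chronicity_evidence(FALSE))
  series <- series[order(series$date), , drop = FALSE]
  elevated <- series$value >= elevated_threshold
  n_el <- sum(elevated)
  if (n_el < min_count) return(new_chronicity_evidence(FALSE, qualifying_count = n_el))
  dates <- series$date[elevated]
  if (min_span_days <= 0) {
    return(new_chronicity_evidence(TRUE, dates[1], dates[min(length(dates), max(2L, min_count))],
                                   n_el, as.numeric(dates[length(dates)] - dates[1])))
  }
  for (i in seq_len(length(dates) - 1L)) {
    j <- which(as.numeric(dates - dates[i]) >= min_span_days)
    if (length(j)) {
      j <- min(j)
      return(new_chronicity_evidence(TRUE, dates[i], dates[j], n_el,
                                     as.numeric(dates[j] - dates[i])))
    }
  }
  new_chronicity_evidence(FALSE, qualifying_count = n_el)
}
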