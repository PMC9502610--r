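# Independent oracles: separately coded reference implementations used to
# cross-check the package's classifiers. They share the published constants
# (those are part of the contract) but none of the package's code paths.

# CKD-EPI 2009 (no race term), creatinine in umol/L, straight-line transcription
oracle_egfr <- function(sex, age, scr) {
  if (sex == "female") {
    k <- 61.9; a <- -0.329; mult <- 1.018
  } else {
    k <- 79.6; a <- -0.411; mult <- 1
  }
  141 * min(scr / k, 1)^a * max(scr / k, 1)^(-1.209) * 0.993^age * mult
}

# chronicity by exhaustive pair enumeration plus the recency condition
oracle_persistent_low <- function(values, dates, threshold = 60,
                                  span = 90, censor = NULL) {
  if (length(values) == 0) return(FALSE)
  ord <- order(dates)
  values <- values[ord]; dates <- dates[ord]
  if (is.null(censor)) censor <- rep("none", length(values))
  censor <- censor[ord]
  low <- values < threshold & censor != "above_limit"
  if (!low[length(low)]) return(FALSE)
  for (i in seq_along(values)) {
    for (j in seq_along(values)) {
      if (i < j && low[i] && low[j] &&
          as.numeric(dates[j] - dates[i]) >= span) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# default renal code prefixes, re-declared here on purpose
.oracle_renal_prefixes <- list(
  ICD10AM = c("N18", "N19", "N02", "N03", "N04", "N05", "N07", "N08", "N11",
              "N14", "N15", "N16", "Q61", "Z49", "Z940", "Z992"),
  ICPC2 = c("U99", "U88"))
.oracle_dialysis <- list(ICD10AM = c("Z49", "Z992"), ICPC2 = "U59",
                         ICD10AM_procedure = "13100", MBS = c("13100", "13103"))
.oracle_transplant <- list(ICD10AM = "Z940", ICD10AM_procedure = "36503",
                           MBS = "36503", ICPC2 = character())
.oracle_stage_map <- list(
  ICD10AM = c(N181 = 1, N182 = 2, N183 = 3, N184 = 4, N185 = 5),
  ICPC2 = c(U9901 = 1, U9902 = 2, U9903 = 3, U9904 = 4, U9905 = 5))

.oracle_match <- function(codes, systems, prefixes) {
  vapply(seq_along(codes), function(i) {
    pfx <- prefixes[[systems[i]]]
    if (is.null(pfx) || length(pfx) == 0) return(FALSE)
    any(startsWith(toupper(gsub(".", "", codes[i], fixed = TRUE)), pfx))
  }, logical(1))
}

# Brute-force CKD classification: a direct transcription of the rule
# disjunction (RRT codes OR laboratory staging OR CKD-related codes),
# independent of the package's classifier.
# `rec` is a list: sex, birth_date, labs (tibble: analyte, value, date,
# censor), codes (tibble: system, code, date), procedures (tibble: system,
# code, date).
oracle_classify_ckd <- function(rec, variant = "stage1_plus",
                                as_of = as.Date("2021-02-07")) {
  labs <- rec$labs[rec$labs$date <= as_of, , drop = FALSE]
  codes <- rec$codes[rec$codes$date <= as_of, , drop = FALSE]
  procs <- rec$procedures[rec$procedures$date <= as_of, , drop = FALSE]

  all_codes <- c(codes$code, procs$code)
  all_sys <- c(codes$system, procs$system)
  if (length(all_codes) &&
      (any(.oracle_match(all_codes, all_sys, .oracle_dialysis)) ||
       any(.oracle_match(all_codes, all_sys, .oracle_transplant)))) {
    return(list(pooled = TRUE, stage = "RRT"))
  }

  # eGFR points: computed from creatinine; reported values only on other days
  cr <- labs[labs$analyte == "serum_creatinine", , drop = FALSE]
  age_at <- function(d) as.numeric(d - rec$birth_date) / 365.25
  pts <- data.frame(date = as.Date(character()), egfr = numeric(),
                    censor = character())
  if (nrow(cr)) {
    keep <- age_at(cr$date) >= 18
    cr <- cr[keep, , drop = FALSE]
    if (nrow(cr)) {
      pts <- rbind(pts, data.frame(
        date = cr$date,
        egfr = round(vapply(seq_len(nrow(cr)), function(i) {
          oracle_egfr(rec$sex, age_at(cr$date[i]), cr$value[i])
        }, numeric(1)), 1),
        censor = "none"))
    }
  }
  rep_ <- labs[labs$analyte == "egfr_reported" & !labs$date %in% pts$date, ,
               drop = FALSE]
  if (nrow(rep_)) {
    pts <- rbind(pts, data.frame(date = rep_$date, egfr = rep_$value,
                                 censor = rep_$censor))
  }
  pts <- pts[pts$egfr > 0, , drop = FALSE]
  pts <- pts[order(pts$date), , drop = FALSE]
  latest <- if (nrow(pts)) pts$egfr[nrow(pts)] else NA_real_

  if (nrow(pts) && oracle_persistent_low(pts$egfr, pts$date, censor = pts$censor)) {
    stage <- if (latest < 15) "CKD5" else if (latest < 30) "CKD4"
             else if (latest < 45) "CKD3b" else "CKD3a"
    return(list(pooled = TRUE, stage = stage))
  }

  if (variant != "stage3a_plus") {
    ua <- labs[labs$analyte == "uacr", , drop = FALSE]
    ua <- ua[order(ua$date), , drop = FALSE]
    elevated <- ua$value >= 3
    ok <- sum(elevated) >= 2
    if (ok && variant == "stringent_uacr") {
      dts <- ua$date[elevated]
      ok <- FALSE
      for (i in seq_along(dts)) for (j in seq_along(dts)) {
        if (i < j && as.numeric(dts[j] - dts[i]) >= 90) ok <- TRUE
      }
    }
    if (ok && (is.na(latest) || latest >= 60)) {
      stage <- if (is.na(latest) || latest >= 90) "CKD1" else "CKD2"
      return(list(pooled = TRUE, stage = stage))
    }
  }

  if (nrow(codes) && any(.oracle_match(codes$code, codes$system,
                                       .oracle_renal_prefixes))) {
    renal <- codes[.oracle_match(codes$code, codes$system,
                                 .oracle_renal_prefixes), , drop = FALSE]
    implied <- vapply(seq_len(nrow(renal)), function(i) {
      map <- .oracle_stage_map[[renal$system[i]]]
      norm <- toupper(gsub(".", "", renal$code[i], fixed = TRUE))
      hit <- names(map)[startsWith(norm, names(map))]
      if (length(hit)) unname(map[hit[1]]) else NA_real_
    }, numeric(1))
    if (any(!is.na(implied))) {
      keep <- which(!is.na(implied))
      latest_dt <- max(renal$date[keep])
      idx <- max(implied[keep][renal$date[keep] == latest_dt])
      stage <- c("CKD1", "CKD2", "CKD3a", "CKD4", "CKD5")[idx]
      return(list(pooled = TRUE, stage = stage))
    }
    return(list(pooled = TRUE, stage = "none"))
  }
  list(pooled = FALSE, stage = "none")
}

# Random small-record generator for the oracle-equivalence check: builds one
# multi-patient cohort plus the per-patient record lists the oracle consumes.
random_ckd_records <- function(n, seed) {
  set.seed(seed)
  as_of <- as.Date("2021-02-07")
  code_pool <- data.frame(
    system = c(rep("ICD10AM", 10), rep("ICPC2", 3)),
    code = c("N181", "N182", "N183", "N184", "N185", "N189", "Z491", "Z940",
             "E11", "I10", "U99", "U9904", "T90"),
    stringsAsFactors = FALSE)
  recs <- lapply(seq_len(n), function(i) {
    id <- sprintf("R%05d", i)
    sex <- sample(c("male", "female"), 1)
    age <- runif(1, 25, 85)
    birth <- as_of - round(age * 365.25)
    n_cr <- sample(0:4, 1)
    n_ua <- sample(0:2, 1)
    n_code <- sample(0:4, 1)
    lab_dates <- as_of - sample(0:1000, n_cr + n_ua, replace = FALSE)
    labs <- tibble::tibble(
      patient_id = id,
      analyte = c(rep("serum_creatinine", n_cr), rep("uacr", n_ua)),
      value = c(round(ckdphen:::ckd_epi_inverse(sex, age, runif(n_cr, 8, 120)), 1),
                round(exp(runif(n_ua, log(0.5), log(40))), 2)),
      units = c(rep("umol/L", n_cr), rep("mg/mmol", n_ua)),
      date = lab_dates, censor = "none")
    picks <- code_pool[sample(nrow(code_pool), n_code, replace = TRUE), ,
                       drop = FALSE]
    codes <- tibble::tibble(
      patient_id = id, system = picks$system, code = picks$code,
      date = as_of - sample(0:1000, n_code, replace = TRUE),
      setting = as.character(ifelse(picks$system == "ICD10AM", "hospital",
                                    "primary_care")))
    list(id = id, sex = sex, birth = birth, labs = labs, codes = codes)
  })
  cohort <- ehr_cohort(
    demographics = tibble::tibble(
      patient_id = vapply(recs, `[[`, "", "id"),
      sex = vapply(recs, `[[`, "", "sex"),
      birth_date = as.Date(vapply(recs, function(r) as.character(r$birth), ""))),
    labs = dplyr::bind_rows(lapply(recs, `[[`, "labs")),
    codes = dplyr::bind_rows(lapply(recs, `[[`, "codes")))
  oracle_recs <- lapply(recs, function(r) {
    list(sex = r$sex, birth_date = r$birth, labs = r$labs, codes = r$codes,
         procedures = tibble::tibble(patient_id = character(),
                                     system = character(), code = character(),
                                     date = as.Date(character())))
  })
  names(oracle_recs) <- vapply(recs, `[[`, "", "id")
  list(cohort = cohort, records = oracle_recs, as_of = as_of)
}
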