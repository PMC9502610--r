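# Small construction helpers used across the suite.

d0 <- as.Date("2020-01-01")

lab_rows <- function(dates, analyte, values, censor = "none",
                     patient_id = "P1") {
  units <- c(serum_creatinine = "umol/L", egfr_reported = "mL/min/1.73m2",
             uacr = "mg/mmol", hba1c = "mmol/mol")[analyte]
  tibble::tibble(patient_id = patient_id, analyte = analyte, value = values,
                 units = unname(units), date = as.Date(dates), censor = censor)
}

code_rows <- function(dates, system, codes, patient_id = "P1") {
  tibble::tibble(patient_id = patient_id, system = system, code = codes,
                 date = as.Date(dates),
                 setting = ifelse(system == "ICD10AM", "hospital", "primary_care"))
}

obs_rows <- function(dates, kind, values, patient_id = "P1") {
  tibble::tibble(patient_id = patient_id, kind = kind, value = values,
                 date = as.Date(dates))
}

med_rows <- function(dates, atc, patient_id = "P1") {
  tibble::tibble(patient_id = patient_id, atc_code = atc, date = as.Date(dates))
}

proc_rows <- function(dates, system, codes, patient_id = "P1") {
  tibble::tibble(patient_id = patient_id, system = system, code = codes,
                 date = as.Date(dates))
}

mini_cohort <- function(labs = NULL, observations = NULL, codes = NULL,
                        medications = NULL, procedures = NULL,
                        patient_id = "P1", sex = "female",
                        birth_date = as.Date("1960-06-15")) {
  ehr_cohort(
    demographics = tibble::tibble(patient_id = patient_id, sex = sex,
                                  birth_date = birth_date),
    labs = labs, observations = observations, codes = codes,
    medications = medications, procedures = procedures)
}

# eGFR target -> creatinine via the package's closed-form inverse; used only
# to construct inputs, never as an expectation.
scr_for_egfr <- function(egfr, sex = "female", age = 60) {
  ckdphen:::ckd_epi_inverse(sex, age, egfr)
}
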