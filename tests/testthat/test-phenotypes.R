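as_of_test <- as.Date("2021-02-07")
acfg <- function(variant = "stage1_plus") {
  algorithm_config(variant = variant, as_of = as_of_test)
}

test_that("RRT classification: transplant dominance, maintenance rule, episodic guard", {
  # one transplant procedure code is enough
  co <- mini_cohort(procedures = proc_rows(as_of_test - 400,
                                           "ICD10AM_procedure", "36503"))
  r <- classify_rrt(co, acfg())
  expect_true(r$rrt); expect_equal(r$rrt_modality, "transplant")
  # 5 haemodialysis codes in the last month -> maintenance haemodialysis
  co <- mini_cohort(codes = code_rows(as_of_test - seq(2, 30, by = 7),
                                      "ICD10AM", "Z49.1"))
  r <- classify_rrt(co, acfg())
  expect_true(r$rrt); expect_equal(r$rrt_modality, "haemodialysis")
  # a single dialysis code two years back: RRT yes, modality unspecified
  co <- mini_cohort(codes = code_rows(as_of_test - 730, "ICD10AM", "Z49.1"))
  r <- classify_rrt(co, acfg())
  expect_true(r$rrt); expect_equal(r$rrt_modality, "unspecified")
  # enumeration over event-count x recency: the maintenance label needs
  # >= 3 dialysis events inside the 90-day window
  for (n_recent in 0:4) {
    for (n_old in 0:2) {
      dates <- c(as_of_test - seq_len(n_recent) * 10,
                 as_of_test - 200 - seq_len(n_old) * 30)
      if (length(dates) == 0) next
      co <- mini_cohort(codes = code_rows(dates, "ICD10AM", "Z49.1"))
      r <- classify_rrt(co, acfg())
      expect_true(r$rrt)
      expect_equal(r$rrt_modality,
                   if (n_recent >= 3) "haemodialysis" else "unspecified",
                   info = paste(n_recent, n_old))
    }
  }
  # transplant still dominates an active dialysis pattern
  co <- mini_cohort(codes = dplyr::bind_rows(
    code_rows(as_of_test - c(5, 12, 19, 26), "ICD10AM", "Z49.2"),
    code_rows(as_of_test - 100, "ICD10AM", "Z94.0")))
  expect_equal(classify_rrt(co, acfg())$rrt_modality, "transplant")
})

test_that("single elevated uACR with one preserved eGFR is no CKD (G2A0 rule)", {
  co <- mini_cohort(labs = dplyr::bind_rows(
    lab_rows(as_of_test - 100, "uacr", 5),
    lab_rows(as_of_test - 90, "serum_creatinine",
             scr_for_egfr(75, age = 60.4))))
  res <- classify_ckd(co, acfg())
  expect_false(res$pooled_positive)
  expect_equal(as.character(res$stage), "none")
})

test_that("persistent low eGFR stages from the most recent value", {
  co <- mini_cohort(labs = lab_rows(
    as_of_test - c(150, 30), "serum_creatinine",
    scr_for_egfr(c(50, 48), age = 60)))
  res <- classify_ckd(co, acfg())
  expect_equal(as.character(res$stage), "CKD3a")
  expect_equal(res$basis, "egfr_criteria")
})

test_that("code-only CKD is pooled-positive, staged only by stage-implying codes", {
  co <- mini_cohort(codes = code_rows(as_of_test - 50, "ICD10AM", "N18.9"))
  res <- classify_ckd(co, acfg())
  expect_true(res$pooled_positive)
  expect_equal(as.character(res$stage), "none")
  expect_equal(res$basis, "ckd_related_codes")
  co2 <- mini_cohort(codes = code_rows(as_of_test - 50, "ICD10AM", "N18.3"))
  res2 <- classify_ckd(co2, acfg())
  expect_equal(as.character(res2$stage), "CKD3a")
  expect_true(grepl("code_implied_stage", res2$basis))
  # laboratory evidence always wins over a code-implied stage
  co3 <- mini_cohort(labs = lab_rows(
    as_of_test - c(200, 10), "serum_creatinine",
    scr_for_egfr(c(20, 22), age = 60)),
    codes = code_rows(as_of_test - 50, "ICD10AM", "N18.3"))
  expect_equal(as.character(classify_ckd(co3, acfg())$stage), "CKD4")
})

test_that("definition variants behave per the sensitivity analysis", {
  # two elevated uACR 30 days apart, preserved eGFR 75-78
  co <- mini_cohort(labs = dplyr::bind_rows(
    lab_rows(as_of_test - c(130, 100), "uacr", c(5, 6)),
    lab_rows(as_of_test - c(120, 20), "serum_creatinine",
             scr_for_egfr(c(75, 78), age = 60))))
  expect_equal(as.character(classify_ckd(co, acfg())$stage), "CKD2")
  expect_false(classify_ckd(co, acfg("stringent_uacr"))$pooled_positive)
  expect_false(classify_ckd(co, acfg("stage3a_plus"))$pooled_positive)
  # with a 120-day gap the stringent variant is satisfied too
  co2 <- mini_cohort(labs = dplyr::bind_rows(
    lab_rows(as_of_test - c(220, 100), "uacr", c(5, 6)),
    lab_rows(as_of_test - c(120, 20), "serum_creatinine",
             scr_for_egfr(c(75, 78), age = 60))))
  expect_equal(as.character(classify_ckd(co2, acfg("stringent_uacr"))$stage), "CKD2")
  # albuminuria with eGFR >= 90 (or absent) is stage 1
  co3 <- mini_cohort(labs = lab_rows(as_of_test - c(220, 100), "uacr", c(5, 6)))
  expect_equal(as.character(classify_ckd(co3, acfg())$stage), "CKD1")
})

test_that("diabetes needs repeated elevation, a medication, or a code", {
  lab <- function(values) lab_rows(as_of_test - seq_along(values) * 60,
                                   "hba1c", values)
  r <- classify_t2dm(mini_cohort(labs = lab(c(60, 62))), acfg())
  expect_true(r$positive); expect_equal(r$basis, "labs")
  # one historic spike among normals, nothing else -> no diabetes
  r <- classify_t2dm(mini_cohort(labs = lab(c(60, 40, 41, 39))), acfg())
  expect_false(r$positive)
  r <- classify_t2dm(mini_cohort(medications = med_rows(as_of_test - 30, "A10BA02")),
                     acfg())
  expect_true(r$positive); expect_equal(r$basis, "medications")
  r <- classify_t2dm(mini_cohort(codes = code_rows(as_of_test - 30, "ICPC2", "T90")),
                     acfg())
  expect_true(r$positive); expect_equal(r$basis, "codes")
})

test_that("hypertension requires two elevated readings on distinct dates, or codes/meds", {
  bp <- function(days, sys, dia) dplyr::bind_rows(
    obs_rows(as_of_test - days, "systolic_bp", sys),
    obs_rows(as_of_test - days, "diastolic_bp", dia))
  r <- classify_hypertension(mini_cohort(observations = bp(c(60, 30),
                                                           c(150, 145), c(80, 85))),
                             acfg())
  expect_true(r$positive); expect_equal(r$basis, "observations")
  expect_false(classify_hypertension(
    mini_cohort(observations = bp(30, 160, 100)), acfg())$positive)
  # two elevated readings on the SAME date do not qualify
  same_day <- dplyr::bind_rows(obs_rows(rep(as_of_test - 30, 2), "systolic_bp",
                                        c(150, 155)))
  expect_false(classify_hypertension(mini_cohort(observations = same_day),
                                     acfg())$positive)
  # enumeration over reading sets of size <= 4 against the two-distinct-date rule
  set.seed(7)
  for (trial in 1:40) {
    n <- sample(0:4, 1)
    if (n == 0) next
    days <- sample(1:5, n, replace = TRUE)
    sys <- sample(c(120, 150), n, replace = TRUE)
    co <- mini_cohort(observations = obs_rows(as_of_test - days, "systolic_bp", sys))
    expected <- length(unique(days[sys >= 140])) >= 2
    expect_equal(classify_hypertension(co, acfg())$positive, expected,
                 info = paste(trial))
  }
  expect_true(classify_hypertension(
    mini_cohort(codes = code_rows(as_of_test - 10, "ICD10AM", "I10")),
    acfg())$positive)
  expect_true(classify_hypertension(
    mini_cohort(medications = med_rows(as_of_test - 10, "C09AA02")),
    acfg())$positive)
})

test_that("cardiovascular disease is code-only", {
  r <- classify_cvd(mini_cohort(codes = code_rows(as_of_test - 10, "ICD10AM", "I21")),
                    acfg())
  expect_true(r$positive); expect_equal(r$basis, "codes")
  # cardiovascular medications alone never qualify
  expect_false(classify_cvd(
    mini_cohort(medications = med_rows(as_of_test - 10, "C07AB02")),
    acfg())$positive)
  expect_false(classify_cvd(mini_cohort(), acfg())$positive)
})

test_that("the at-risk flag ORs comorbidities, renal codes and the risk score", {
  t2 <- mini_cohort(medications = med_rows(as_of_test - 30, "A10BA02"))
  expect_true(at_risk_ckd(t2, acfg())$at_risk)
  aki <- mini_cohort(codes = code_rows(as_of_test - 30, "ICD10AM", "N17"))
  expect_true(at_risk_ckd(aki, acfg())$at_risk)
  empty <- mini_cohort()
  expect_false(at_risk_ckd(empty, acfg())$at_risk)
  # > 15 percent is a strict inequality
  expect_true(at_risk_ckd(empty, acfg(),
                          external_cvd_risk = c(P1 = 16))$at_risk)
  expect_false(at_risk_ckd(empty, acfg(),
                           external_cvd_risk = c(P1 = 15))$at_risk)
})

test_that("classification is deterministic and temporally local", {
  g <- generate_validation_cohort(n_per_subgroup = rep(4, 6), seed = 11)
  l1 <- classify_cohort(g$cohort, acfg())
  l2 <- classify_cohort(g$cohort, acfg())
  expect_identical(l1, l2)
  # adding entries after as_of never changes labels at as_of
  future_lab <- lab_rows(as_of_test + 200, "serum_creatinine", 400,
                         patient_id = patient_ids(g$cohort)[1])
  co2 <- ehr_cohort(demographics = g$cohort$demographics,
                    labs = dplyr::bind_rows(g$cohort$labs, future_lab),
                    observations = g$cohort$observations,
                    codes = g$cohort$codes,
                    medications = g$cohort$medications,
                    procedures = g$cohort$procedures)
  expect_equal(classify_cohort(co2, acfg()), l1)
})

test_that("stage is exclusive and RRT suppresses numeric stages", {
  # dialysis codes plus deep lab CKD: RRT wins
  co <- mini_cohort(
    labs = lab_rows(as_of_test - c(300, 10), "serum_creatinine",
                    scr_for_egfr(c(9, 8), age = 60)),
    codes = code_rows(as_of_test - seq(5, 40, by = 7), "ICD10AM", "Z49.1"))
  res <- classify_ckd(co, acfg())
  expect_equal(as.character(res$stage), "RRT")
  g <- generate_validation_cohort(n_per_subgroup = rep(4, 6), seed = 3)
  labels <- classify_cohort(g$cohort, acfg())
  expect_false(anyNA(labels$ckd_stage))
  expect_true(all(labels$ckd_stage[labels$rrt] == "RRT"))
})

test_that("adding a concept code never flips a positive to negative", {
  g <- generate_validation_cohort(n_per_subgroup = rep(3, 6), seed = 5)
  before <- classify_cohort(g$cohort, acfg())
  extra <- code_rows(rep(as_of_test - 15, length(patient_ids(g$cohort))),
                     "ICD10AM", "E11",
                     patient_id = patient_ids(g$cohort))
  co2 <- ehr_cohort(demographics = g$cohort$demographics,
                    labs = g$cohort$labs,
                    observations = g$cohort$observations,
                    codes = dplyr::bind_rows(g$cohort$codes, extra),
                    medications = g$cohort$medications,
                    procedures = g$cohort$procedures)
  after <- classify_cohort(co2, acfg())
  expect_true(all(after$t2dm >= before$t2dm))
  expect_true(all(after$ckd_pooled >= before$ckd_pooled))
  expect_true(all(after$hypertension >= before$hypertension))
  expect_true(all(after$cvd >= before$cvd))
})
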