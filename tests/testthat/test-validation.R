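test_that("confusion counts match hand enumeration and reject mismatched sets", {
  gold <- c(a = TRUE, b = FALSE, c = TRUE)
  expect_error(confusion_counts(gold, c(a = TRUE, b = FALSE, d = TRUE)),
               "patient sets differ")
  set.seed(9)
  ids <- sprintf("p%02d", 1:20)
  g <- stats::setNames(sample(c(TRUE, FALSE), 20, replace = TRUE), ids)
  p <- stats::setNames(sample(c(TRUE, FALSE), 20, replace = TRUE), sample(ids))
  cc <- confusion_counts(g, p)
  p_aligned <- p[ids]
  expect_equal(cc$tp, sum(g & p_aligned))
  expect_equal(cc$fp, sum(!g & p_aligned))
  expect_equal(cc$fn, sum(g & !p_aligned))
  expect_equal(cc$tn, sum(!g & !p_aligned))
  ident <- confusion_counts(g, g)
  expect_equal(ident$fp + ident$fn, 0L)
})

test_that("accuracy report reproduces the Wald interval and flags undefined metrics", {
  cc <- structure(list(tp = 130, fp = 20, fn = 10, tn = 40),
                  class = "confusion_counts")
  rep <- tidy(accuracy_report(cc))
  se <- rep[rep$metric == "sensitivity", ]
  expect_equal(se$estimate, 130 / 140, tolerance = 1e-10)
  expect_equal(se$conf.low, 0.8859, tolerance = 1e-3)
  expect_equal(se$conf.high, 0.9712, tolerance = 1e-3)
  # zero-width interval at p = 1 (the "100% (100 to 100%)" pattern)
  perfect <- structure(list(tp = 50, fp = 0, fn = 0, tn = 10),
                       class = "confusion_counts")
  t_perfect <- tidy(accuracy_report(perfect))
  expect_equal(t_perfect$conf.low[1], 1); expect_equal(t_perfect$conf.high[1], 1)
  # AUC is the mean of Se and Sp
  g <- glance(accuracy_report(cc))
  expect_equal(g$auc, (g$sensitivity + g$specificity) / 2)
  expect_equal(glance(accuracy_report(structure(
    list(tp = 93, fp = 27, fn = 7, tn = 73), class = "confusion_counts")))$auc,
    0.83)
  # zero denominator -> undefined, not NaN
  nodeneg <- accuracy_report(structure(list(tp = 5, fp = 0, fn = 2, tn = 0),
                                       class = "confusion_counts"))
  sp <- tidy(nodeneg)[tidy(nodeneg)$metric == "specificity", ]
  expect_true(sp$undefined); expect_true(is.na(sp$estimate))
})

test_that("Wald interval width shrinks like 1/sqrt(n)", {
  widths <- vapply(c(50, 200, 800, 3200), function(n) {
    cc <- structure(list(tp = round(0.8 * n), fn = n - round(0.8 * n),
                         fp = 1, tn = 1), class = "confusion_counts")
    t <- tidy(accuracy_report(cc))
    se <- t[t$metric == "sensitivity", ]
    se$conf.high - se$conf.low
  }, numeric(1))
  ratios <- widths[-length(widths)] / widths[-1]
  expect_equal(ratios, rep(2, 3), tolerance = 0.05)
})

test_that("Buderer sample size reproduces the published design numbers", {
  res <- buderer_sample_size(0.95, 0.90, prevalence = 0.5)
  expect_equal(res$n_required, 277L)
  expect_equal(res$n_sensitivity, 146L)
  expect_equal(res$n_specificity, 277L)
  # symmetric under (Se, P) <-> (Sp, 1-P)
  a <- buderer_sample_size(0.8, 0.95, prevalence = 0.3)
  b <- buderer_sample_size(0.95, 0.8, prevalence = 0.7)
  expect_equal(a$n_sensitivity, b$n_specificity)
  expect_equal(a$n_specificity, b$n_sensitivity)
  # p(1-p) is maximised at 1/2
  n_half <- buderer_sample_size(0.5, 0.9, prevalence = 0.5)$n_sensitivity
  for (se in c(0.6, 0.75, 0.9, 0.99)) {
    expect_lte(buderer_sample_size(se, 0.9, prevalence = 0.5)$n_sensitivity,
               n_half)
  }
  expect_error(buderer_sample_size(0.95, 0.9, prevalence = 1), "prevalence")
})

test_that("Cohen's kappa matches the closed form and its bounds", {
  perf <- cohens_kappa(diag(c(30, 20, 10)))
  expect_equal(perf$kappa, 1)
  expect_equal(perf$raw_agreement, 1)
  k <- cohens_kappa(matrix(c(40, 5, 10, 45), 2))
  expect_equal(k$po, 0.85)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.70)
  # kappa = 1 iff all off-diagonal counts vanish
  k2 <- cohens_kappa(matrix(c(40, 1, 10, 45), 2))
  expect_lt(k2$kappa, 1)
  expect_error(cohens_kappa(matrix(0, 2, 2)), "counts")
  expect_error(cohens_kappa(matrix(1:6, 2, 3)), "square")
})

test_that("kappa is near zero for independent raters", {
  set.seed(101)
  r1 <- sample(c(TRUE, FALSE), 10000, replace = TRUE, prob = c(0.4, 0.6))
  r2 <- sample(c(TRUE, FALSE), 10000, replace = TRUE, prob = c(0.7, 0.3))
  k <- cohens_kappa(table(r1, r2))
  expect_lt(abs(k$kappa), 0.03)
})

test_that("stage confusion matrix tallies correctly and collapses consistently", {
  stages <- c("none", "CKD1", "CKD2", "CKD3a", "CKD3b", "CKD4", "CKD5", "RRT")
  ids <- sprintf("p%02d", 1:30)
  set.seed(4)
  g <- stats::setNames(sample(stages, 30, replace = TRUE), ids)
  p <- stats::setNames(sample(stages, 30, replace = TRUE), ids)
  m <- stage_confusion_matrix(g, p)
  # brute-force recount
  for (a in stages) for (b in stages) {
    expect_equal(m[a, b], sum(g == a & p == b))
  }
  expect_equal(sum(m), 30)
  # identical maps -> diagonal
  m_id <- stage_confusion_matrix(g, g)
  expect_equal(sum(m_id) - sum(diag(m_id)), 0)
  # one-vs-rest collapse equals accuracy on collapsed labels
  cc <- stage_one_vs_rest(m, "CKD3a")
  direct <- confusion_counts(g == "CKD3a", p[names(g)] == "CKD3a")
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               unclass(direct)[c("tp", "fp", "fn", "tn")])
  expect_error(stage_confusion_matrix(c(a = "CKD9"), c(a = "none")), "unknown")
})

test_that("subgroup assignment is an eligibility-gated partition", {
  g <- generate_validation_cohort(n_per_subgroup = rep(5, 6), seed = 13)
  sg <- subgroup_assign(g$cohort)
  expect_equal(sort(unique(as.character(sg$subgroup))), as.character(1:6))
  expect_equal(nrow(sg), length(patient_ids(g$cohort)))
  expect_false(anyNA(sg$subgroup))
  # a thin record is ineligible
  co <- mini_cohort(labs = lab_rows(d0 + c(0, 10), "serum_creatinine", c(80, 82)))
  expect_equal(as.character(subgroup_assign(co)$subgroup), "ineligible")
})

test_that("stratified sampling is reproducible, within-group, and degenerate-safe", {
  sub <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:260),
    subgroup = factor(c(rep("1", 100), rep("2", 120), rep("3", 40)),
                      levels = c(as.character(1:6), "ineligible")))
  expect_warning(s1 <- stratified_sample(sub, n_per_group = 60, seed = 42),
                 "taking all")
  s2 <- suppressWarnings(stratified_sample(sub, n_per_group = 60, seed = 42))
  expect_identical(s1, s2)
  expect_equal(as.vector(table(droplevels(s1$subgroup))), c(60, 60, 40))
  # selections come from their own subgroup
  for (grp in c("1", "2", "3")) {
    expect_true(all(s1$patient_id[s1$subgroup == grp] %in%
                    sub$patient_id[sub$subgroup == grp]))
  }
  s3 <- suppressWarnings(stratified_sample(sub, n_per_group = 60, seed = 43))
  expect_false(identical(s1$patient_id, s3$patient_id))
})

test_that("coded-stage comparator averages discordant systems with ceiling", {
  # ICD stage 3 vs ICPC stage 4 -> ceil(3.5) = 4
  co <- mini_cohort(codes = dplyr::bind_rows(
    code_rows(d0, "ICD10AM", "N18.3"),
    code_rows(d0 + 5, "ICPC2", "U9904")))
  expect_equal(as.character(coded_stage_classifier(co)$coded_stage), "CKD4")
  # single-system passthrough
  co2 <- mini_cohort(codes = code_rows(d0, "ICD10AM", "N18.5"))
  expect_equal(as.character(coded_stage_classifier(co2)$coded_stage), "CKD5")
  # within a system, the most severe stage-implying code wins
  co3 <- mini_cohort(codes = code_rows(d0 + c(0, 10), "ICD10AM",
                                       c("N18.2", "N18.4")))
  expect_equal(as.character(coded_stage_classifier(co3)$coded_stage), "CKD4")
  # RRT codes dominate
  co4 <- mini_cohort(codes = dplyr::bind_rows(
    code_rows(d0, "ICD10AM", "N18.3"),
    code_rows(d0 + 1, "ICD10AM", "Z49.1")))
  expect_equal(as.character(coded_stage_classifier(co4)$coded_stage), "RRT")
  # no renal codes, or only unstaged ones -> none
  expect_equal(as.character(coded_stage_classifier(mini_cohort(
    codes = code_rows(d0, "ICD10AM", "E11")))$coded_stage), "none")
  expect_equal(as.character(coded_stage_classifier(mini_cohort(
    codes = code_rows(d0, "ICD10AM", "N18.9")))$coded_stage), "none")
})

test_that("phenotype_accuracy joins labels and reports per disease", {
  gold <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                         t2dm = c(TRUE, TRUE, FALSE, FALSE),
                         cvd = c(TRUE, FALSE, TRUE, FALSE))
  pred <- tibble::tibble(patient_id = c("d", "c", "b", "a"),
                         t2dm = c(FALSE, FALSE, TRUE, TRUE),
                         cvd = c(FALSE, FALSE, FALSE, TRUE))
  acc <- phenotype_accuracy(gold, pred)
  t2 <- acc[acc$disease == "t2dm" & acc$metric == "sensitivity", ]
  expect_equal(t2$estimate, 1)
  cv <- acc[acc$disease == "cvd" & acc$metric == "sensitivity", ]
  expect_equal(cv$estimate, 0.5)
})
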