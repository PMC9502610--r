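#' Confusion counts against a gold standard
#'
#' Standard 2x2 cross-tabulation of predicted against gold-standard binary
#' labels. Both inputs are named logical vectors keyed by patient id (or
#' unnamed vectors of equal length, matched positionally); the patient sets
#' must coincide.
#'
#' @param gold named logical vector of gold-standard labels.
#' @param predicted named logical vector of algorithm labels.
#' @return a `confusion_counts` object with fields `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion_counts(c(a = TRUE, b = FALSE), c(a = TRUE, b = TRUE))
confusion_counts <- function(gold, predicted) {
  if (!is.null(names(gold)) || !is.null(names(predicted))) {
    extra_g <- setdiff(names(gold), names(predicted))
    extra_p <- setdiff(names(predicted), names(gold))
    if (length(extra_g) || length(extra_p)) {
      stop("patient sets differ; only in gold: {",
           paste(utils::head(extra_g, 5), collapse = ", "),
           "}; only in predicted: {",
           paste(utils::head(extra_p, 5), collapse = ", "), "}", call. = FALSE)
    }
    predicted <- predicted[names(gold)]
  } else if (length(gold) != length(predicted)) {
    stop("gold and predicted must have the same length", call. = FALSE)
  }
  stopifnot(is.logical(gold), is.logical(predicted),
            !anyNA(gold), !anyNA(predicted))
  structure(list(tp = sum(gold & predicted), fp = sum(!gold & predicted),
                 fn = sum(gold & !predicted), tn = sum(!gold & !predicted)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

.wald_ci <- function(p, n, z) {
  if (n == 0) return(c(NA_real_, NA_real_))
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Diagnostic accuracy with asymptotic confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive values from
#' 2x2 confusion counts, each with the asymptotic (Wald) confidence interval
#' `p +/- z * sqrt(p(1-p)/n)` clipped to `[0, 1]` — note the interval has
#' zero width at p = 0 or 1 — plus the two-class AUC `(Se + Sp) / 2`.
#' A metric whose denominator is zero is returned as `NA` with an
#' `undefined` flag rather than propagating NaN.
#'
#' @param counts a [confusion_counts()] object.
#' @param alpha two-sided type-I error for the intervals (default 0.05).
#' @return an `accuracy_report` object; see [tidy.accuracy_report()] for the
#'   tibble form and [glance.accuracy_report()] for a one-row summary.
#' @export
#' @examples
#' tidy(accuracy_report(structure(list(tp = 130, fp = 20, fn = 10, tn = 40),
#'                                class = "confusion_counts")))
accuracy_report <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "confusion_counts"))
  z <- stats::qnorm(1 - alpha / 2)
  mk <- function(num, den) {
    if (den == 0) {
      list(estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
           n = 0L, undefined = TRUE)
    } else {
      p <- num / den
      ci <- .wald_ci(p, den, z)
      list(estimate = p, conf.low = ci[1], conf.high = ci[2],
           n = as.integer(den), undefined = FALSE)
    }
  }
  se <- mk(counts$tp, counts$tp + counts$fn)
  sp <- mk(counts$tn, counts$tn + counts$fp)
  metrics <- list(
    sensitivity = se, specificity = sp,
    ppv = mk(counts$tp, counts$tp + counts$fp),
    npv = mk(counts$tn, counts$tn + counts$fn)
  )
  auc <- if (!se$undefined && !sp$undefined) (se$estimate + sp$estimate) / 2 else NA_real_
  structure(list(metrics = metrics, auc = auc, alpha = alpha, counts = counts),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> (alpha =", x$alpha, ")\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy an accuracy report
#'
#' @param x an [accuracy_report()].
#' @param ... unused.
#' @return tibble with `metric`, `estimate`, `conf.low`, `conf.high`, `n`,
#'   `undefined`.
#' @export
tidy.accuracy_report <- function(x, ...) {
  purrr::imap_dfr(x$metrics, function(m, nm) {
    tibble::tibble(metric = nm, estimate = m$estimate, conf.low = m$conf.low,
                   conf.high = m$conf.high, n = m$n, undefined = m$undefined)
  })
}

#' Glance at an accuracy report
#'
#' @param x an [accuracy_report()].
#' @param ... unused.
#' @return one-row tibble: point estimates, AUC and total count.
#' @export
glance.accuracy_report <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(sensitivity = m$sensitivity$estimate,
                 specificity = m$specificity$estimate,
                 ppv = m$ppv$estimate, npv = m$npv$estimate, auc = x$auc,
                 n = x$counts$tp + x$counts$fp + x$counts$fn + x$counts$tn)
}

#' Buderer sample size for diagnostic accuracy
#'
#' Sample size needed to estimate sensitivity and specificity to a target
#' margin of error: the sensitivity-driven size is
#' `ceiling(z^2 Se (1-Se) / d^2 / P)` and the specificity-driven size
#' `ceiling(z^2 Sp (1-Sp) / d^2 / (1-P))`, with the ceiling applied after
#' the prevalence division; the requirement is their maximum. With the
#' conventional z = 1.96, expected sensitivity 0.95, specificity 0.90,
#' prevalence 0.50 and margin 0.05 this gives 146, 277 and 277.
#'
#' @param sensitivity,specificity expected test accuracy, in (0, 1).
#' @param prevalence expected disease prevalence, in (0, 1) exclusive.
#' @param alpha two-sided type-I error (default 0.05).
#' @param margin target half-width of the confidence interval (default 0.05).
#' @param z normal quantile to use; default 1.96 for `alpha = 0.05`
#'   (set `z = NULL` for the exact `qnorm(1 - alpha/2)`).
#' @return tibble with `n_sensitivity`, `n_specificity`, `n_required`.
#' @export
#' @examples
#' buderer_sample_size(0.95, 0.90, prevalence = 0.5)
buderer_sample_size <- function(sensitivity, specificity, prevalence,
                                alpha = 0.05, margin = 0.05, z = 1.96) {
  stopifnot(sensitivity > 0, sensitivity < 1, specificity > 0, specificity < 1,
            margin > 0, alpha > 0, alpha < 1)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(z)) z <- stats::qnorm(1 - alpha / 2)
  n_se <- ceiling(z^2 * sensitivity * (1 - sensitivity) / margin^2 / prevalence)
  n_sp <- ceiling(z^2 * specificity * (1 - specificity) / margin^2 / (1 - prevalence))
  tibble::tibble(n_sensitivity = as.integer(n_se), n_specificity = as.integer(n_sp),
                 n_required = as.integer(max(n_se, n_sp)))
}

#' Cohen's kappa and raw agreement
#'
#' Chance-corrected inter-rater agreement from a square cross-tabulation of
#' two raters' categorical calls: `kappa = (po - pe) / (1 - pe)` with the
#' expected agreement `pe` from the marginal products. When `pe = 1` (both
#' raters degenerate on one category) kappa is undefined and returned as
#' `NA`.
#'
#' @param table square numeric matrix of counts (rater 1 in rows, rater 2 in
#'   columns, shared categories), or anything coercible via `as.matrix`.
#' @return a `kappa_agreement` object with `raw_agreement`, `kappa`, `po`,
#'   `pe`, `n`; use [tidy.kappa_agreement()] for a tibble.
#' @export
#' @examples
#' cohens_kappa(matrix(c(40, 5, 10, 45), 2))
cohens_kappa <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != ncol(m)) stop("agreement table must be square", call. = FALSE)
  if (any(m < 0) || sum(m) == 0) stop("agreement table must hold counts", call. = FALSE)
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (isTRUE(all.equal(pe, 1))) NA_real_ else (po - pe) / (1 - pe)
  structure(list(raw_agreement = po, kappa = kappa, po = po, pe = pe, n = n),
            class = "kappa_agreement")
}

#' @export
print.kappa_agreement <- function(x, ...) {
  cat(sprintf("<kappa_agreement> raw agreement %.3f, kappa %.3f (n=%d)\n",
              x$raw_agreement, x$kappa, x$n))
  invisible(x)
}

#' Tidy a kappa result
#' @param x a [cohens_kappa()] result.
#' @param ... unused.
#' @return one-row tibble.
#' @export
tidy.kappa_agreement <- function(x, ...) {
  tibble::tibble(raw_agreement = x$raw_agreement, kappa = x$kappa,
                 po = x$po, pe = x$pe, n = x$n)
}

#' Stage-level confusion matrix
#'
#' Cross-tabulation of gold-standard against predicted CKD stage over the
#' fixed eight-level set (none, CKD1-CKD5, RRT; RRT is mutually exclusive
#' with the numeric stages). Per-stage one-vs-rest confusion counts are
#' derivable with [stage_one_vs_rest()].
#'
#' @param gold,predicted vectors (character or factor) over the stage levels,
#'   named by patient id or matched positionally.
#' @return a `stage_confusion` matrix (gold in rows, predicted in columns).
#' @export
stage_confusion_matrix <- function(gold, predicted) {
  if (!is.null(names(gold)) && !is.null(names(predicted))) {
    if (!setequal(names(gold), names(predicted))) {
      stop("patient sets differ between gold and predicted stages", call. = FALSE)
    }
    predicted <- predicted[names(gold)]
  }
  gold <- as.character(gold); predicted <- as.character(predicted)
  bad <- setdiff(unique(c(gold, predicted)), .ckd_stage_levels)
  if (length(bad)) {
    stop("unknown stage categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- table(factor(gold, levels = .ckd_stage_levels),
             factor(predicted, levels = .ckd_stage_levels))
  structure(unclass(m), dimnames = list(gold = .ckd_stage_levels,
                                        predicted = .ckd_stage_levels),
            class = c("stage_confusion", "matrix"))
}

#' One-vs-rest collapse of a stage confusion matrix
#'
#' @param x a [stage_confusion_matrix()].
#' @param stage the stage treated as positive.
#' @return a [confusion_counts()] object.
#' @export
stage_one_vs_rest <- function(x, stage) {
  stopifnot(inherits(x, "stage_confusion"), stage %in% .ckd_stage_levels)
  i <- match(stage, .ckd_stage_levels)
  structure(list(tp = x[i, i], fp = sum(x[-i, i]), fn = sum(x[i, -i]),
                 tn = sum(x[-i, -i])), class = "confusion_counts")
}

#' Assign validation subgroups
#'
#' Stratification of a classified cohort into the six validation subgroups,
#' in priority order (the first matching subgroup wins, making the subgroups
#' disjoint):
#' \enumerate{
#'   \item at risk of CKD with no CKD (pooled-negative);
#'   \item CKD stages 1 to 3a;
#'   \item CKD stages 3b to 4;
#'   \item CKD stage 5 or RRT;
#'   \item two or more coded (ICD/ICPC) comorbidities among diabetes,
#'     hypertension, cardiovascular disease;
#'   \item three or more chronic-disease medications.
#' }
#' Patients with fewer than 3 laboratory-plus-observation entries are
#' ineligible.
#'
#' @param cohort an [ehr_cohort()].
#' @param labels classifier output from [classify_cohort()] under the default
#'   configuration (computed if omitted).
#' @param config a [load_config()] object.
#' @return tibble with `patient_id`, `subgroup` (factor `"1"`..`"6"`,
#'   `"ineligible"`).
#' @export
subgroup_assign <- function(cohort, labels = NULL, config = load_config()) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (is.null(labels)) labels <- classify_cohort(cohort, algorithm_config(config = config))
  as_of <- .cohort_as_of(cohort)
  recs <- split_records(cohort)
  labels <- labels[match(names(recs), labels$patient_id), , drop = FALSE]
  sub <- purrr::map2_chr(recs, seq_along(recs), function(rec, i) {
    if (nrow(rec$labs) + nrow(rec$observations) < 3) return("ineligible")
    lab <- labels[i, ]
    stage <- as.character(lab$ckd_stage)
    if (lab$at_risk && !lab$ckd_pooled) return("1")
    if (stage %in% c("CKD1", "CKD2", "CKD3a")) return("2")
    if (stage %in% c("CKD3b", "CKD4")) return("3")
    if (stage %in% c("CKD5", "RRT")) return("4")
    codes <- .upto(rec$codes, as_of)
    coded <- sum(vapply(c("t2dm", "hypertension", "cvd"), function(concept) {
      nrow(codes) > 0L && any(match_code(codes$code, codes$system, concept, config))
    }, logical(1)))
    if (coded >= 2) return("5")
    meds <- .upto(rec$medications, as_of)
    if (nrow(meds) &&
        sum(match_code(meds$atc_code, "ATC", "chronic_disease_med", config)) >= 3) {
      return("6")
    }
    "ineligible"
  })
  tibble::tibble(patient_id = names(recs),
                 subgroup = factor(sub, levels = c(as.character(1:6), "ineligible")))
}

#' Stratified random sample of a validation cohort
#'
#' Uniform sampling without replacement within each subgroup, reproducible
#' under the seed. A subgroup smaller than `n_per_group` is returned whole
#' with a warning.
#'
#' @param subgroups tibble from [subgroup_assign()] (columns `patient_id`,
#'   `subgroup`).
#' @param n_per_group target number per subgroup (default 60).
#' @param seed integer RNG seed.
#' @return tibble with `patient_id`, `subgroup` for the selected patients.
#' @export
stratified_sample <- function(subgroups, n_per_group = 60, seed = 1L) {
  stopifnot(all(c("patient_id", "subgroup") %in% names(subgroups)))
  eligible <- subgroups[subgroups$subgroup != "ineligible", , drop = FALSE]
  set.seed(seed)
  picked <- lapply(split(eligible$patient_id, droplevels(eligible$subgroup)),
                   function(ids) {
    if (length(ids) < n_per_group) {
      warning("subgroup with only ", length(ids), " member(s); taking all",
              call. = FALSE)
      return(sort(ids))
    }
    sort(sample(ids, n_per_group))
  })
  tibble::tibble(
    patient_id = unlist(picked, use.names = FALSE),
    subgroup = factor(rep(names(picked), lengths(picked)),
                      levels = levels(subgroups$subgroup)))
}

#' Administrative-code CKD stage comparator
#'
#' The coded-diagnosis baseline the phenotype algorithms are compared
#' against: a CKD stage derived from ICD and ICPC codes alone. Within each
#' coding system the most severe stage-implying code wins; when the two
#' systems imply different stages the ordinal mean is taken and rounded up
#' (`ceiling`), on the 1-5 scale with stage 3 mapped to CKD3a. Any RRT code
#' dominates and yields `"RRT"`. Renal codes that imply no particular stage
#' leave the comparator at `"none"`.
#'
#' @param cohort an [ehr_cohort()].
#' @param config a [load_config()] object.
#' @param as_of review date (`NULL` = latest entry date).
#' @return tibble with `patient_id`, `coded_stage` (factor over the 8 levels).
#' @export
coded_stage_classifier <- function(cohort, config = load_config(), as_of = NULL) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  if (is.null(as_of)) as_of <- .cohort_as_of(cohort)
  recs <- split_records(cohort)
  stage <- purrr::map_chr(recs, function(rec) {
    codes <- .upto(rec$codes, as_of)
    procs <- .upto(rec$procedures, as_of)
    all_codes <- c(codes$code, procs$code)
    all_systems <- c(codes$system, procs$system)
    if (length(all_codes) &&
        any(match_code(all_codes, all_systems, "rrt_dialysis", config) |
            match_code(all_codes, all_systems, "rrt_transplant", config))) {
      return("RRT")
    }
    if (nrow(codes) == 0L) return("none")
    implied <- code_implied_stage(codes$code, codes$system, config)
    per_system <- vapply(c("ICD10AM", "ICPC2"), function(sys) {
      v <- implied[codes$system == sys]
      if (all(is.na(v))) NA_integer_ else max(v, na.rm = TRUE)
    }, integer(1))
    per_system <- per_system[!is.na(per_system)]
    if (length(per_system) == 0L) return("none")
    .stage_from_index[ceiling(mean(per_system))]
  })
  tibble::tibble(patient_id = names(recs),
                 coded_stage = factor(stage, levels = .ckd_stage_levels))
}

#' Per-disease accuracy of predicted labels against a gold standard
#'
#' Convenience wrapper joining a gold-standard label table with classifier
#' output and producing one [accuracy_report()] row set per disease.
#'
#' @param gold tibble with `patient_id` and logical columns per disease.
#' @param predicted tibble with `patient_id` and the same logical columns.
#' @param diseases character vector of label columns shared by both tables.
#' @param alpha CI level parameter passed to [accuracy_report()].
#' @return tibble: `disease`, `metric`, `estimate`, `conf.low`, `conf.high`,
#'   `n`, `undefined`, plus an `auc` row per disease.
#' @export
phenotype_accuracy <- function(gold, predicted,
                               diseases = intersect(names(gold), names(predicted)),
                               alpha = 0.05) {
  diseases <- setdiff(diseases, "patient_id")
  purrr::map_dfr(diseases, function(d) {
    g <- stats::setNames(as.logical(gold[[d]]), gold$patient_id)
    p <- stats::setNames(as.logical(predicted[[d]]), predicted$patient_id)
    rep <- accuracy_report(confusion_counts(g, p), alpha = alpha)
    dplyr::bind_cols(tibble::tibble(disease = d), tidy(rep)) %>%
      dplyr::bind_rows(tibble::tibble(disease = d, metric = "auc",
                                      estimate = rep$auc, conf.low = NA_real_,
                                      conf.high = NA_real_,
                                      n = as.integer(sum(!is.na(g))),
                                      undefined = is.na(rep$auc)))
  })
}
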