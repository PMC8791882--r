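# Patient-grouped k-fold cross-validation with Wilson confidence
# intervals. Folds partition patients (all teeth of a patient share a
# fold); per-fold AUC, sensitivity and specificity are averaged and the
# Wilson interval is computed with n = the number of independent patients —
# the conservative convention of the original analysis.

#' Partition patients into k folds of near-equal size
#'
#' Deterministic given the seed; fold sizes differ by at most one patient.
#'
#' @param patient_ids character vector of distinct patient identifiers.
#' @param k number of folds (default 10; must not exceed the number of
#'   patients).
#' @param seed integer seed for the shuffle.
#' @return list of `k` disjoint character vectors covering all patients.
#' @export
patient_kfold <- function(patient_ids, k = 10, seed = 1) {
  ids <- unique(as.character(patient_ids))
  if (k < 1 || k > length(ids)) {
    stop("k must lie between 1 and the number of patients (", length(ids), ")")
  }
  set.seed(seed)
  shuffled <- sample(ids)
  split(shuffled, rep_len(seq_len(k), length(ids)))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney form with average ranks, so tied scores count one half: the
#' probability that a randomly chosen lost tooth scores above a randomly
#' chosen retained tooth.
#'
#' @param scores numeric predictions (higher = more likely lost).
#' @param labels binary outcomes (1 = lost).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc undefined: both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# candidate classification thresholds: midpoints between adjacent distinct
# scores (classify lost when score > threshold)
pt_thresholds <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  (u[-1] + u[-length(u)]) / 2
}

#' Sensitivity and specificity at a classification threshold policy
#'
#' A tooth is classified as "lost" when its score strictly exceeds the
#' threshold. The default policy picks the threshold maximising Youden's J
#' (sensitivity + specificity - 1) on training scores, breaking ties toward
#' the higher threshold (favouring specificity, the clinically preferred
#' error direction here); policy `"fixed"` uses `threshold` as given. When
#' all scores coincide no score exceeds the single candidate threshold, so
#' the degenerate result is sensitivity 0, specificity 1.
#'
#' @param scores test-set scores.
#' @param labels test-set binary outcomes (1 = lost).
#' @param policy `"youden"` or `"fixed"`.
#' @param train_scores,train_labels data used to set the Youden threshold
#'   (default: the test data itself).
#' @param threshold the cut used under `policy = "fixed"` (default 0.5).
#' @return list: `sensitivity`, `specificity`, `threshold`.
#' @export
sens_spec <- function(scores, labels, policy = c("youden", "fixed"),
                      train_scores = scores, train_labels = labels,
                      threshold = 0.5) {
  policy <- match.arg(policy)
  labels <- as.integer(labels)
  if (policy == "youden") {
    tl <- as.integer(train_labels)
    if (length(unique(tl)) < 2) {
      stop("threshold selection requires both classes in the training data")
    }
    cand <- pt_thresholds(train_scores)
    j <- vapply(cand, function(t) {
      mean(train_scores[tl == 1] > t) + mean(train_scores[tl == 0] <= t) - 1
    }, numeric(1))
    threshold <- max(cand[j >= max(j) - 1e-12])
  }
  pred <- scores > threshold
  sens <- if (any(labels == 1)) mean(pred[labels == 1]) else NA_real_
  spec <- if (any(labels == 0)) mean(!pred[labels == 0]) else NA_real_
  list(sensitivity = sens, specificity = spec, threshold = threshold)
}

#' Wilson score interval for a proportion
#'
#' Obtained by inverting the score test; unlike the Wald interval it
#' respects `[0, 1]` and is nondegenerate at the boundaries.
#'
#' @param p proportion-scale value in `[0, 1]`.
#' @param n number of independent units (>= 1).
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`.
#' @export
wilson_ci <- function(p, n, level = 0.95) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  z <- stats::qnorm((1 + level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - hw), upper = min(1, centre + hw))
}

#' Patient-grouped cross-validation of the model-tree
#'
#' Splits patients into `k` folds ([patient_kfold()]); for each fold, fits
#' the tree on the other folds' teeth, predicts marginal probabilities for
#' the held-out patients' teeth (unseen patients carry no BLUP), and
#' computes AUC plus sensitivity/specificity at a threshold chosen on the
#' training fold. Metric means are unweighted across folds; Wilson intervals
#' use `n` = the number of independent patients. Folds whose test outcomes
#' are single-class are skipped with a warning; more than three skipped
#' folds is an error. Optionally bootstrap variable selection is repeated
#' inside each training fold instead of validating a fixed variable set.
#'
#' @param cohort a complete-case [perio_cohort()] with both outcome classes.
#' @param selected_vars the partitioning variables to validate.
#' @param fit_config a [fit_config()].
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param threshold_policy `"youden"` (set on the training fold) or
#'   `"fixed"` at 0.5.
#' @param reselect re-run [select_variables()] within each training fold
#'   (with `n_boot_reselect` replicates) before fitting.
#' @param n_boot_reselect bootstrap replicates per fold when `reselect`.
#' @param level confidence level for the Wilson intervals.
#' @return object of class `cv_result`: `k`, `folds` (per-fold data.frame
#'   with `auc`, `sensitivity`, `specificity`, `threshold`, `n_teeth`,
#'   `skipped`), `mean` (named vector), `ci` (matrix with rows lower/upper),
#'   `n_patients`, `seed`, `threshold_policy`.
#' @export
cross_validate <- function(cohort, selected_vars,
                           fit_config = periotree::fit_config(), k = 10,
                           seed = 1, threshold_policy = c("youden", "fixed"),
                           reselect = FALSE, n_boot_reselect = 50,
                           level = 0.95) {
  stopifnot(inherits(cohort, "perio_cohort"))
  threshold_policy <- match.arg(threshold_policy)
  if (length(unique(cohort$teeth$lost_by_T2)) < 2) {
    stop("cross-validation requires both outcome classes")
  }
  folds <- patient_kfold(cohort$patients$patient_id, k = k, seed = seed)

  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_pat <- folds[[f]]
    train <- pt_subset_patients(cohort, setdiff(cohort$patients$patient_id, test_pat))
    test <- pt_subset_patients(cohort, test_pat)
    vars_f <- selected_vars
    if (reselect) {
      sel <- select_variables(train, selected_vars, n_boot = n_boot_reselect,
                              fit_config = fit_config, seed = seed + 1000 * f)
      if (length(sel$selected)) vars_f <- sel$selected
    }
    model <- fit_glmm_tree(train, vars_f, fit_config)
    sc_test <- predict(model, test, mode = "marginal")
    y_test <- cohort_data(test)$lost_by_T2
    if (length(unique(y_test)) < 2) {
      warning("fold ", f, " has single-class test outcomes; metrics skipped")
      rows[[f]] <- data.frame(fold = f, auc = NA, sensitivity = NA,
                              specificity = NA, threshold = NA,
                              n_teeth = length(y_test), skipped = TRUE)
      next
    }
    sc_train <- predict(model, train, mode = "marginal")
    y_train <- cohort_data(train)$lost_by_T2
    ss <- sens_spec(sc_test, y_test, policy = threshold_policy,
                    train_scores = sc_train, train_labels = y_train)
    rows[[f]] <- data.frame(fold = f, auc = roc_auc(sc_test, y_test),
                            sensitivity = ss$sensitivity,
                            specificity = ss$specificity,
                            threshold = ss$threshold,
                            n_teeth = length(y_test), skipped = FALSE)
  }
  per_fold <- do.call(rbind, rows)
  if (sum(per_fold$skipped) > 3) {
    stop("more than 3 folds had single-class test outcomes")
  }
  ok <- !per_fold$skipped
  means <- c(auc = mean(per_fold$auc[ok]),
             sensitivity = mean(per_fold$sensitivity[ok]),
             specificity = mean(per_fold$specificity[ok]))
  n_pat <- nrow(cohort$patients)
  ci <- sapply(means, wilson_ci, n = n_pat, level = level)
  structure(list(k = k, folds = per_fold, mean = means, ci = ci,
                 n_patients = n_pat, seed = seed,
                 threshold_policy = threshold_policy, level = level),
            class = "cv_result")
}

# restrict a cohort to a patient subset (order preserved)
pt_subset_patients <- function(cohort, patient_ids) {
  pat <- cohort$patients[cohort$patients$patient_id %in% patient_ids, ]
  teeth <- cohort$teeth[cohort$teeth$patient_id %in% patient_ids, ]
  teeth$bone_loss_cat <- NULL
  perio_cohort(pat, teeth, provenance = cohort$provenance)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold patient-grouped CV, %d patients (%s threshold)\n",
              x$k, x$n_patients, x$threshold_policy))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.2f  (%.0f%% Wilson CI [%.2f; %.2f], n = %d patients)\n",
                m, x$mean[[m]], 100 * x$level, x$ci["lower", m],
                x$ci["upper", m], x$n_patients))
  }
  invisible(x)
}

#' Serialize a cross-validation result to JSON
#'
#' @param cv a `cv_result`.
#' @param path optional output path; JSON string returned when `NULL`.
#' @return JSON string or `path` invisibly.
#' @export
cv_to_json <- function(cv, path = NULL) {
  doc <- list(k = cv$k, n_patients = cv$n_patients, seed = cv$seed,
              threshold_policy = cv$threshold_policy, level = cv$level,
              mean = as.list(cv$mean),
              ci = list(lower = as.list(cv$ci["lower", ]),
                        upper = as.list(cv$ci["upper", ])),
              folds = cv$folds)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null",
                         dataframe = "rows")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
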