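# Patient-grouped cross-validation, metrics, and Wilson intervals.

test_that("patient folds partition and balance to within one patient", {
  ids <- sprintf("P%03d", 1:110)
  folds <- patient_kfold(ids, k = 10, seed = 1)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 11))
  expect_setequal(unlist(folds), ids)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  }
  f107 <- patient_kfold(ids[1:107], k = 10, seed = 2)
  expect_lte(diff(range(lengths(f107))), 1)
  expect_length(patient_kfold(ids, k = 1, seed = 3)[[1]], 110)
  expect_error(patient_kfold(ids[1:5], k = 10), "between 1 and")
})

test_that("rank-based AUC matches the brute-force pairwise oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  # 6-point fixture with one tie across classes
  s <- c(0.1, 0.4, 0.4, 0.6, 0.7, 0.9)
  l <- c(0, 0, 1, 0, 1, 1)
  expect_equal(roc_auc(s, l), pairwise_auc(s, l), tolerance = 1e-12)
  set.seed(30)
  for (i in 1:20) {
    s <- sample(round(runif(30), 1))       # coarse grid forces ties
    l <- rbinom(30, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(roc_auc(s, l), pairwise_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("sensitivity and specificity come out of the confusion table", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1)
  l <- c(1, 1, 0, 1, 0, 1, 0, 0)
  ss <- sens_spec(s, l, policy = "fixed", threshold = 0.5)
  # at 0.5: predicted positive = {0.9,0.8,0.7,0.6} -> TP=3 FP=1 FN=1 TN=3
  expect_equal(ss$sensitivity, 3 / 4)
  expect_equal(ss$specificity, 3 / 4)

  perfect <- sens_spec(c(1, 1, 0, 0), c(1, 1, 0, 0), policy = "fixed",
                       threshold = 0.5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  flat <- sens_spec(rep(0.3, 6), c(1, 0, 1, 0, 1, 0), policy = "fixed",
                    threshold = 0.3)
  expect_equal(flat$sensitivity, 0)   # nothing exceeds the single threshold
  expect_equal(flat$specificity, 1)
})

test_that("the Youden threshold is chosen on the training data only", {
  train_s <- c(0.1, 0.2, 0.6, 0.7, 0.8, 0.9)
  train_l <- c(0, 0, 0, 1, 1, 1)
  test_s <- c(0.63, 0.75)
  test_l <- c(0, 1)
  ss <- sens_spec(test_s, test_l, policy = "youden",
                  train_scores = train_s, train_labels = train_l)
  expect_equal(ss$threshold, 0.65)    # midpoint of 0.6 and 0.7
  expect_equal(ss$sensitivity, 1)
  expect_equal(ss$specificity, 1)
})

test_that("Wilson intervals reproduce the printed confidence limits", {
  expect_equal(round(wilson_ci(0.77, 110), 2), c(lower = 0.68, upper = 0.84))
  expect_equal(round(wilson_ci(0.73, 110), 2), c(lower = 0.64, upper = 0.80))
  expect_equal(round(wilson_ci(0.79, 110), 2), c(lower = 0.70, upper = 0.86))
  expect_equal(wilson_ci(1, 50)[["upper"]], 1)
  expect_gt(wilson_ci(1, 50)[["lower"]], 0.9)
  ci <- wilson_ci(0.5, 10)
  expect_lt(ci[["lower"]], ci[["upper"]])
})

test_that("cross-validation never leaks a patient across train and test", {
  co <- generate_cohort(sim_config(n_patients = 50, seed = 40))
  folds <- patient_kfold(co$patients$patient_id, k = 5, seed = 7)
  for (f in seq_along(folds)) {
    train_ids <- setdiff(co$patients$patient_id, folds[[f]])
    expect_length(intersect(train_ids, folds[[f]]), 0)
  }
  cv <- cross_validate(co, model_vars, fit_config(quadrature_points = 7),
                       k = 5, seed = 7)
  expect_equal(cv$k, 5)
  expect_true(all(cv$folds$n_teeth > 0))
  expect_true(all(cv$mean >= 0 & cv$mean <= 1))
  expect_true(all(cv$ci["lower", ] <= cv$ci["upper", ]))
  # reproducibility
  cv2 <- cross_validate(co, model_vars, fit_config(quadrature_points = 7),
                        k = 5, seed = 7)
  expect_equal(cv$folds, cv2$folds)
  js <- jsonlite::fromJSON(cv_to_json(cv))
  expect_equal(js$mean$auc, unname(cv$mean["auc"]))
})

test_that("leave-one-patient-out degenerates into the documented single-class error", {
  co <- generate_cohort(sim_config(n_patients = 12, seed = 41,
                                   mechanism = "constant",
                                   baseline_rate = 0.02))
  expect_error(
    suppressWarnings(cross_validate(co, model_vars,
                                    fit_config(quadrature_points = 5),
                                    k = 12, seed = 2)),
    "single-class")
})
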