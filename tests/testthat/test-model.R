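test_that("a constructed separable cohort is learned essentially perfectly", {
  pair <- small_cohort_pair(seed = 7)
  f_tr <- cohort_features(pair$train)
  m <- hrd_fit(f_tr, pair$train$labels, seed = 3)
  expect_s3_class(m, "hrd_model")
  expect_gt(m$train_auc, 1 - 1e-6)
  pred <- predict(m, cohort_features(pair$test))
  ev <- hrd_evaluate(pair$test$labels$label, pred$probability)
  expect_gt(ev$auc, 0.95)
  ## broom-style accessors agree with the stored state
  td <- tidy(m)
  expect_equal(td$estimate, m$svm_weights)
  expect_equal(glance(m)$regularization_c, m$regularization_c)
})

test_that("a feature vector at the scaler means scores at the model's bias point", {
  pair <- small_cohort_pair(seed = 21)
  m <- hrd_fit(cohort_features(pair$train), pair$train$labels, seed = 1)
  at_mean <- tibble::as_tibble(as.list(stats::setNames(m$scaler_means,
                                                       m$feature_order)))
  at_mean$sample_id <- "mean_sample"
  at_mean$assay <- m$assay
  pred <- predict(m, at_mean)
  expect_equal(pred$decision_value, m$svm_bias, tolerance = 1e-12)
  expect_equal(pred$probability,
               plogis(m$calibration_params[1] * m$svm_bias +
                        m$calibration_params[2]),
               tolerance = 1e-12)
})

test_that("probabilities are monotone in a positively weighted feature and duplicate-stable", {
  pair <- small_cohort_pair(seed = 33)
  m <- hrd_fit(cohort_features(pair$train), pair$train$labels, seed = 2)
  expect_gt(m$svm_weights[m$feature_order == "del5_mh"], 0)
  withr::local_seed(5)
  base <- cohort_features(pair$test)[1:5, ]
  for (step in c(1, 3, 10)) {
    bumped <- dplyr::mutate(base, del5_mh = .data$del5_mh + step)
    expect_true(all(predict(m, bumped)$probability >=
                      predict(m, base)$probability))
  }
  dup <- dplyr::bind_rows(base, base)
  p <- predict(m, dup)$probability
  expect_equal(p[1:5], p[6:10])
})

test_that("status calls use an inclusive threshold and honor overrides", {
  expect_equal(hrd_classify(c(0.5, 0.4999, 0.9, 0)),
               c("HRD", "HRP", "HRD", "HRP"))
  expect_equal(hrd_classify(0.6, threshold = 0.7), "HRP")
  expect_error(hrd_classify(1.4), "probability")
})

test_that("evaluation metrics match their definitions and a brute-force AUC", {
  perfect <- hrd_evaluate(rep(c("HRD", "HRP"), each = 5),
                          c(runif(5, 0.6, 1), runif(5, 0, 0.4)))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)
  mixed <- hrd_evaluate(c("HRD", "HRP", "HRD"), c(0.9, 0.8, 0.7))
  expect_equal(mixed$auc, 0.5)
  withr::local_seed(99)
  for (i in 1:20) {
    truth <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (length(unique(truth)) < 2) next
    score <- sample(seq(0, 1, 0.05), 40, replace = TRUE)  # heavy ties
    expect_equal(auc_rank(truth, score), oracle_auc(truth, score))
  }
  expect_message(
    ev <- hrd_evaluate(rep("HRD", 3), c(0.9, 0.8, 0.7)),
    "single class")
  expect_true(is.na(ev$auc))
  expect_equal(ev$f1, 1)
})

test_that("degenerate training inputs are rejected or repaired loudly", {
  pair <- small_cohort_pair(seed = 41, n_train = 6)
  f <- cohort_features(pair$train)
  one_class <- dplyr::mutate(pair$train$labels, label = "HRD")
  expect_error(hrd_fit(f, one_class), "at least 2 samples per class")
  expect_warning(hrd_fit(f, pair$train$labels, n_folds = 10, seed = 1),
                 "reducing folds")
})

test_that("models serialize to JSON and round-trip exactly", {
  pair <- small_cohort_pair(seed = 55)
  f_tr <- cohort_features(pair$train)
  m <- hrd_fit(f_tr, pair$train$labels, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_hrd_model(m, path)
  m2 <- read_hrd_model(path)
  for (field in c("scaler_means", "scaler_sds", "svm_weights", "svm_bias",
                  "calibration_params", "regularization_c", "threshold",
                  "feature_order", "cancer_type", "assay", "training_seed")) {
    expect_identical(m2[[field]], m[[field]], label = field)
  }
  f_te <- cohort_features(pair$test)
  expect_identical(predict(m2, f_te), predict(m, f_te))
})

test_that("assay mismatches are an explicit error with an override", {
  pair <- small_cohort_pair(seed = 61, n_train = 8, n_test = 4)
  m <- suppressWarnings(hrd_fit(cohort_features(pair$train),
                                pair$train$labels, seed = 1))
  f_wes <- dplyr::mutate(cohort_features(pair$test), assay = "WES")
  expect_error(predict(m, f_wes), "override_assay")
  expect_s3_class(predict(m, f_wes, override_assay = TRUE), "tbl_df")
})
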