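# Confusion matrices, the percent metric suite, macro averaging, and the
# holdout + cross-validation protocol over the preset registry.

test_that("confusion matrix counts truth-by-estimate", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2))
  expect_equal(unclass(unname(as.matrix(cm))),
               matrix(c(1, 0, 1, 1), 2))
  # perfect prediction is diagonal; row sums are class supports
  y <- rep(c("a", "b", "c"), times = c(5, 3, 2))
  cmp <- confusion_matrix(y, y)
  expect_equal(diag(as.matrix(cmp)), c(a = 5, b = 3, c = 2))
  expect_equal(sum(as.matrix(cmp)) - sum(diag(as.matrix(cmp))), 0)
  expect_equal(unname(rowSums(as.matrix(cmp))), c(5, 3, 2))
  expect_error(confusion_matrix(c("a", "b"), c("a", "z"), levels = c("a", "b")),
               "outside the declared levels")
  expect_error(confusion_matrix(1:3, 1:2), "equal length")
})

test_that("binary one-vs-rest metrics match hand arithmetic", {
  # TP=9, FN=1, FP=2, TN=8
  cm <- matrix(c(9, 2, 1, 8), 2, dimnames = list(c("pos", "neg"),
                                                 c("pos", "neg")))
  rep <- per_class_metrics(cm)
  pos <- rep$per_class[rep$per_class$class == "pos", ]
  expect_equal(pos$recall, 90)
  expect_equal(pos$precision, 100 * 9 / 11)
  expect_equal(round(pos$precision, 2), 81.82)
  expect_equal(rep$accuracy, 85)
  expect_equal(pos$fpr, 20)
  expect_equal(pos$fnr, 10)
})

test_that("metric identities hold on random confusion matrices", {
  withr::with_seed(4, {
    for (i in 1:10) {
      k <- sample(2:6, 1)
      cm <- matrix(rpois(k * k, 8), k)
      rep <- per_class_metrics(cm)
      pc <- rep$per_class
      ok <- !is.na(pc$recall)
      expect_equal(pc$recall[ok] + pc$fnr[ok], rep(100, sum(ok)))
      expect_equal(rep$accuracy, 100 * sum(diag(cm)) / sum(cm))
      # F1 between min and max of precision and recall
      both <- !is.na(pc$f1)
      expect_true(all(pc$f1[both] >= pmin(pc$precision, pc$recall)[both] - 1e-9))
      expect_true(all(pc$f1[both] <= pmax(pc$precision, pc$recall)[both] + 1e-9))
      expect_equal(rep$macro$recall, macro_average(pc$recall))
    }
  })
})

test_that("when precision equals recall the F1 equals both", {
  expect_equal(f1_score(99.06, 99.06), 99.06)
  expect_true(is.na(f1_score(NA, 50)))
  expect_true(is.na(f1_score(0, 0)))
})

test_that("F1 of precision 97.15 and recall 97.3 rounds to 97.2", {
  expect_equal(round(f1_score(97.15, 97.3), 1), 97.2)
})

test_that("macro average is the unweighted mean of defined values", {
  expect_equal(macro_average(c(98.2, 100, 100, 97.1, 100)), 99.06)
  expect_equal(round(macro_average(c(97.7, 99.4, 98.2, 95.4, 96.5, 96.6)), 1),
               97.3)
  expect_equal(macro_average(c(80, 80, 80)), 80)
  expect_equal(macro_average(c(90, NA, 70)), 80)
  expect_true(is.na(macro_average(c(NA_real_, NA_real_))))
})

test_that("zero-denominator metrics are undefined, not zero", {
  # class "b" never occurs in truth and is never predicted
  cm <- matrix(c(5, 0, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  rep <- per_class_metrics(cm)
  b <- rep$per_class[rep$per_class$class == "b", ]
  expect_true(is.na(b$recall))
  expect_true(is.na(b$precision))
  expect_gt(rep$n_undefined, 0)
  expect_equal(rep$macro$recall, 100) # only the defined class contributes
})

test_that("the registry exposes all ten presets and rejects unknown ids", {
  expect_setequal(list_presets()$preset,
                  c("c_svm", "w_knn", "q_svm", "lda", "f_knn", "knb",
                    "mg_svm", "sda", "co_knn", "c_knn"))
  # hyphenated display-style ids normalize
  expect_equal(classifier_spec("Q-SVM")$preset, "q_svm")
  expect_equal(classifier_spec("Co-KNN")$preset, "co_knn")
  expect_error(classifier_spec("made_up"), "unknown classifier preset")
  # hyperparameters are overridable
  expect_equal(classifier_spec("w_knn", k = 3)$hyperparams$k, 3)
})

test_that("every preset fits and predicts on small multiclass data", {
  sf <- synthetic_features(n_per_class = 15, k_classes = 3, d_informative = 3,
                           d_noise = 2, separation = 4, seed = 8)
  fm <- validate_features(sf$features)
  for (p in list_presets()$preset) {
    model <- fit_classifier(classifier_spec(p, seed = 1), fm$x, fm$y)
    pred <- predict_classifier(model, fm$x)
    expect_length(pred, nrow(fm$x))
    expect_true(all(levels(pred) == levels(fm$y)), info = p)
    # training-set accuracy on well-separated data should be far above chance
    expect_gt(mean(pred == fm$y), 0.7, label = paste0(p, " train accuracy"))
  }
})

test_that("SVM presets reach 100% holdout on linearly separable data", {
  df <- separable_table(n_per_class = 25, d_noise = 2)
  for (p in c("c_svm", "q_svm", "mg_svm")) {
    ev <- evaluate_classifier(df, p, cv_folds = 5, seed = 3)
    expect_equal(ev$holdout$accuracy, 100, info = p)
  }
})

test_that("label-permuted data scores near chance", {
  sf <- synthetic_features(n_per_class = 60, k_classes = 3, d_informative = 3,
                           d_noise = 2, separation = 0, seed = 10)
  ev <- evaluate_classifier(sf$features, "f_knn", cv_folds = 5, seed = 2)
  # chance is 33.3%; allow generous binomial noise on 36 held-out samples
  expect_lt(ev$holdout$accuracy, 61)
  expect_gt(ev$holdout$accuracy, 8)
})

test_that("evaluation reports both surfaces and is seed-deterministic", {
  df <- separable_table(n_per_class = 20, d_noise = 3)
  ev1 <- evaluate_classifier(df, "f_knn", cv_folds = 5, seed = 9)
  ev2 <- evaluate_classifier(df, "f_knn", cv_folds = 5, seed = 9)
  expect_identical(tidy(ev1, "holdout"), tidy(ev2, "holdout"))
  expect_identical(glance(ev1)$cv_accuracy, glance(ev2)$cv_accuracy)
  expect_equal(tidy(ev1, "cv")$surface[1], "cv")
  rt <- report_table(list(ev1))
  expect_named(rt, c("classifier", "recall", "precision", "fnr", "time",
                     "f1", "accuracy"))
  expect_s3_class(autoplot(confusion_matrix(c("a", "b"), c("a", "b"))),
                  "ggplot")
})
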