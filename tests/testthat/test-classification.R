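# Small deterministic cohorts for classifier checks are built in code via
# simulate_cohort(); a "separable" cohort pushes the group means far apart.

separable_cohort <- function(seed = 1) {
  params <- default_cohort_params()
  params$lc_mean <- ifelse(params$group == "patient", 0.8, 1.6)
  params$rc_mean <- ifelse(params$group == "patient", 0.8, 1.6)
  params$lc_sd <- 0.02; params$rc_sd <- 0.02
  simulate_cohort(params, seed = seed)
}

null_cohort <- function(seed = 1) {
  params <- default_cohort_params()
  params$lc_mean <- 1.25; params$rc_mean <- 1.25
  params$lc_sd <- 0.08; params$rc_sd <- 0.08
  simulate_cohort(params, seed = seed)
}

test_that("build_features splits 220 subjects 154/33/33, stratified by label", {
  f <- build_features(simulate_cohort(seed = 42), seed = 42)
  sizes <- table(f$partition)
  expect_identical(as.integer(sizes[c("train", "validation", "test")]),
                   c(154L, 33L, 33L))
  by_class <- table(f$partition, f$y)
  expect_true(all(abs(by_class[, "0"] - by_class[, "1"]) <= 1L))
  expect_identical(sum(f$y), 110L)
})

test_that("standardization is fit on the training partition only", {
  f <- build_features(simulate_cohort(seed = 42), seed = 42)
  tr <- f$partition == "train"
  expect_true(all(abs(colMeans(f$x[tr, ])) < 1e-9))
  expect_true(all(abs(apply(f$x[tr, ], 2, sd) - 1) < 1e-9))
  # held-out columns are transformed with the train parameters, so their
  # moments are close to but not exactly standard
  expect_false(all(abs(colMeans(f$x[!tr, ])) < 1e-9))
  # the scaler never changes when validation/test rows are permuted,
  # because it is a function of the training rows alone
  cohort <- simulate_cohort(seed = 42)
  f2 <- build_features(cohort, seed = 42)
  expect_identical(f$scaler, f2$scaler)
})

test_that("splits are reproducible per seed and robust to label shuffles", {
  cohort <- simulate_cohort(seed = 42)
  f1 <- build_features(cohort, seed = 42)
  f2 <- build_features(cohort, seed = 42)
  expect_identical(f1$partition, f2$partition)
  shuffled <- cohort
  set.seed(1); shuffled$group <- sample(shuffled$group)
  f3 <- build_features(shuffled, seed = 42)
  expect_identical(table(f3$partition), table(f1$partition))
  expect_error(build_features(cohort, split = c(0.5, 0.5, 0.5)), "sum to 1")
  broken <- cohort; broken$lc_fd[3] <- NA
  expect_error(build_features(broken), broken$subject_id[3])
})

test_that("every family separates a linearly separable cohort", {
  f <- build_features(separable_cohort(), seed = 42)
  tr <- f$partition == "train"
  for (nm in classifier_names()) {
    clf <- suppressWarnings(
      fit_classifier(nm, f$x[tr, , drop = FALSE], f$y[tr], seed = 42))
    pred <- predict_classifier(clf, f$x[tr, , drop = FALSE])
    acc <- mean(pred$class == f$y[tr])
    expect_equal(acc, 1.0, info = nm)
  }
})

test_that("fitting is deterministic given data and seed", {
  f <- build_features(simulate_cohort(seed = 42), seed = 42)
  tr <- f$partition == "train"
  for (nm in classifier_names()) {
    c1 <- fit_classifier(nm, f$x[tr, ], f$y[tr], seed = 42)
    c2 <- fit_classifier(nm, f$x[tr, ], f$y[tr], seed = 42)
    expect_identical(predict_classifier(c1, f$x[!tr, ])$score,
                     predict_classifier(c2, f$x[!tr, ])$score, info = nm)
  }
  expect_error(fit_classifier("random_forest", f$x[tr, ],
                              rep(1L, sum(tr))), "both classes")
})

test_that("confusion-matrix metrics reproduce the reference worked example", {
  met <- metrics_from_confusion(list(tp = 49, tn = 35, fp = 5, fn = 5))
  expect_equal(round(met$accuracy, 4), 0.8936)
  # control-positive convention swaps the classes
  flipped <- metrics_from_confusion(list(tp = 35, tn = 49, fp = 5, fn = 5))
  expect_equal(flipped$precision, 0.8750)
  expect_equal(flipped$recall, 0.8750)
  expect_equal(flipped$f1, 0.8750)
  expect_equal(flipped$accuracy, met$accuracy)  # accuracy is symmetric
})

test_that("metrics handle perfect and undefined cases explicitly", {
  perfect <- metrics_from_confusion(list(tp = 10, tn = 12, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1,
                                  recall = 1, f1 = 1))
  none_pred <- metrics_from_confusion(list(tp = 0, tn = 10, fp = 0, fn = 5))
  expect_true(is.na(none_pred$precision))  # undefined, not silently 0
  expect_identical(none_pred$recall, 0)
  met <- metrics_from_confusion(list(tp = 7, tn = 9, fp = 3, fn = 2))
  expect_equal(met$f1,
               2 * met$precision * met$recall / (met$precision + met$recall),
               tolerance = 1e-12)
  expect_error(metrics_from_confusion(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "empty")
})

test_that("ROC points are monotone and the trapezoidal AUC is consistent", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.4, 0.3, 0.2)
  labels <- c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L)
  pts <- roc_points(scores, labels)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  # probability interpretation: P(score_pos > score_neg) + ties/2
  set.seed(41)
  s <- runif(300); y <- as.integer(runif(300) < 0.5)
  wilcox_auc <- unname(wilcox.test(s[y == 1], s[y == 0],
                                   exact = FALSE)$statistic /
                       (sum(y == 1) * sum(y == 0)))
  expect_equal(roc_auc(s, y), wilcox_auc, tolerance = 1e-9)
})

test_that("ROC/PR agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  s <- rnorm(120); y <- as.integer(s + rnorm(120) > 0)
  ours <- roc_auc(s, y)
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
  pr <- pr_points(s, y)
  expect_equal(pr$recall[nrow(pr)], 1)
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
})

test_that("random scores give a null AUC near one half", {
  set.seed(47)
  s <- runif(2000); y <- rep(0:1, 1000)
  expect_lt(abs(roc_auc(s, y) - 0.5), 0.05)
})

test_that("cross-validation yields 5 folds of 44 on 220 rows with both classes", {
  f <- build_features(simulate_cohort(seed = 42), seed = 42)
  rep_lr <- cross_validate("logistic_regression", f, k = 5, seed = 42)
  expect_identical(nrow(rep_lr$folds), 5L)
  expect_true(all(rep_lr$folds[, -1] >= 0 & rep_lr$folds[, -1] <= 1))
  expect_identical(names(rep_lr$mean),
                   c("accuracy", "precision", "recall", "f1", "roc_auc"))
})

test_that("perfectly separable data cross-validates at AUC 1 +/- 0", {
  f <- build_features(separable_cohort(), seed = 42)
  rep_xgb <- cross_validate("xgboost", f, k = 5, seed = 42)
  expect_equal(unname(rep_xgb$mean["roc_auc"]), 1)
  expect_equal(unname(rep_xgb$sd["roc_auc"]), 0)
})

test_that("the benchmark detects the published group separation", {
  f <- build_features(simulate_cohort(seed = 42), seed = 42)
  rep_gb <- cross_validate("xgboost", f, k = 5, seed = 42)
  se <- rep_gb$sd[["roc_auc"]] / sqrt(5)
  expect_gt(rep_gb$mean[["roc_auc"]], 0.5 + 3 * se)
})

test_that("on zero-separation cohorts every model hovers at chance", {
  f <- build_features(null_cohort(seed = 5), seed = 42)
  for (nm in classifier_names()) {
    rep_m <- cross_validate(nm, f, k = 5, seed = 42)
    expect_lt(abs(rep_m$mean[["accuracy"]] - 0.5), 0.1)
  }
})

test_that("two same-seed benchmark runs are byte-identical", {
  f <- build_features(simulate_cohort(seed = 42), seed = 42)
  b1 <- benchmark_classifiers(f, k = 5, seed = 42)
  b2 <- benchmark_classifiers(f, k = 5, seed = 42)
  expect_identical(serialize(b1$cv, NULL), serialize(b2$cv, NULL))
  expect_identical(b1$holdout$xgboost$test$confusion,
                   b2$holdout$xgboost$test$confusion)
  expect_identical(sort(b1$cv$rank), 1:6)
})

test_that("feature importance is normalized, ranked and honest about support", {
  cohort <- simulate_cohort(seed = 11)
  # label depends only on the left condyle FD
  cohort$group <- ifelse(cohort$lc_fd > median(cohort$lc_fd),
                         "patient", "control")
  f <- build_features(cohort, seed = 42)
  tr <- f$partition == "train"
  for (nm in c("random_forest", "gradient_boosting", "xgboost")) {
    clf <- fit_classifier(nm, f$x[tr, ], f$y[tr], seed = 42)
    imp <- feature_importance(clf)
    expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
    expect_identical(imp$feature[1], "lc_fd", info = nm)
  }
  # a constant feature gets zero importance
  x2 <- f$x[tr, ]; x2[, "gender"] <- 0
  clf2 <- fit_classifier("xgboost", x2, f$y[tr], seed = 42)
  imp2 <- feature_importance(clf2)
  expect_equal(imp2$importance[imp2$feature == "gender"], 0)
  clf_svm <- fit_classifier("support_vector_machine", f$x[tr, ], f$y[tr])
  expect_error(feature_importance(clf_svm), "unsupported")
})
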