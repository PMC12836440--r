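# Six-classifier benchmark for discriminating TMD patients from controls
# from {age, gender, LC_FD, RC_FD}: standardized features, stratified
# 70/15/15 split, stratified 5-fold cross-validated metrics, ROC/PR
# curves, confusion matrices and tree-ensemble feature importance.

#' The six benchmark classifier families
#'
#' @return Character vector of model identifiers.
#' @export
classifier_names <- function() {
  c("random_forest", "logistic_regression", "support_vector_machine",
    "gradient_boosting", "k_nearest_neighbors", "xgboost")
}

classifier_label <- function(name) {
  c(random_forest = "Random Forest",
    logistic_regression = "Logistic Regression",
    support_vector_machine = "Support Vector Machine",
    gradient_boosting = "Gradient Boosting",
    k_nearest_neighbors = "K-Nearest Neighbors",
    xgboost = "XGBoost")[[name]]
}

# Largest-remainder allocation of `n` units to fractions `fracs`, then
# reconciled against global partition targets so that stratified per-class
# splits still sum to the largest-remainder split of the whole sample.
largest_remainder <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  rem <- raw - base
  extra <- n - sum(base)
  if (extra > 0L) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
  }
  as.integer(base)
}

#' Build the standardized feature matrix and stratified split
#'
#' Encodes gender as male = 0 / female = 1, labels patients as 1 and
#' controls as 0, splits 70/15/15 stratified by label (largest-remainder
#' rounding, reconciled to the whole-sample split sizes), and z-scores
#' every feature column with mean/SD fitted on the training partition
#' only; the same fitted parameters transform the validation and test
#' partitions.
#'
#' @param cohort cohort data frame (`subject_id`, `age`, `gender`,
#'   `group`, `lc_fd`, `rc_fd`).
#' @param split fractions for train/validation/test; must sum to 1.
#' @param seed RNG seed for the shuffle (42 reproduces the reference
#'   protocol).
#' @return Object of class `fd_features`: `x` (standardized numeric
#'   matrix), `y` (0/1 integer labels), `partition` (character vector
#'   train/validation/test), `scaler` (per-column train means and SDs).
#' @export
build_features <- function(cohort, split = c(0.7, 0.15, 0.15), seed = 42L) {
  check_cohort(cohort)
  if (length(split) != 3L || abs(sum(split) - 1) > 1e-9)
    stop("split fractions must have length 3 and sum to 1", call. = FALSE)
  bad <- !stats::complete.cases(cohort[, c("age", "gender", "group",
                                           "lc_fd", "rc_fd")])
  if (any(bad))
    stop("incomplete rows for subjects: ",
         paste(cohort$subject_id[bad], collapse = ", "), call. = FALSE)
  x <- cbind(age = as.numeric(cohort$age),
             gender = as.numeric(cohort$gender == "female"),
             lc_fd = cohort$lc_fd, rc_fd = cohort$rc_fd)
  y <- as.integer(cohort$group == "patient")
  n <- nrow(x)
  part <- character(n)
  global <- largest_remainder(n, split)
  assigned <- c(0L, 0L, 0L)
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      raw <- length(idx) * split
      alloc <- floor(raw)
      # leftover units go to the largest fractional remainders, ties broken
      # toward the partition furthest under its whole-sample target
      for (r in seq_len(length(idx) - sum(alloc))) {
        deficit <- global - (assigned + alloc)
        slot <- order(-(raw - floor(raw)), -deficit)[1L]
        alloc[slot] <- alloc[slot] + 1L
      }
      lab <- rep(c("train", "validation", "test"), times = alloc)
      part[idx] <- lab
      assigned <- assigned + alloc
    }
  })
  tr <- part == "train"
  mu <- colMeans(x[tr, , drop = FALSE])
  sdv <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
  if (any(sdv == 0))
    stop("constant feature column in the training partition: ",
         paste(colnames(x)[sdv == 0], collapse = ", "), call. = FALSE)
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  structure(list(x = xs, y = y, partition = part,
                 scaler = list(mean = mu, sd = sdv), seed = seed),
            class = "fd_features")
}

#' Fit one classifier family
#'
#' Fits the named family at its implementation's documented defaults
#' (random forest: 500 trees; SVM: radial kernel, C = 1; KNN: k = 5;
#' gradient boosting: depth-3 trees, learning rate 0.1, 100 rounds;
#' XGBoost: library defaults, 100 rounds), seeding wherever the family is
#' stochastic so refits are reproducible.
#'
#' @param name one of [classifier_names()].
#' @param x standardized numeric feature matrix (training rows).
#' @param y 0/1 integer labels (1 = patient, the positive class).
#' @param seed RNG seed.
#' @return Object of class `fd_classifier` with a `score()` closure
#'   returning the probability-like score of the positive class.
#' @export
fit_classifier <- function(name, x, y, seed = 42L) {
  name <- match.arg(name, classifier_names())
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  yf <- factor(y, levels = c(0L, 1L))
  fit <- with_seed(seed, switch(name,
    logistic_regression = {
      m <- stats::glm.fit(cbind(1, x), y, family = stats::binomial())
      list(score = function(nx) {
        as.numeric(stats::plogis(cbind(1, nx) %*% m$coefficients))
      })
    },
    random_forest = {
      m <- randomForest::randomForest(x, yf, ntree = 500L)
      list(score = function(nx) {
        unname(stats::predict(m, nx, type = "prob")[, "1"])
      }, model = m)
    },
    support_vector_machine = {
      m <- e1071::svm(x, yf, kernel = "radial", cost = 1, scale = FALSE)
      pos_first <- startsWith(colnames(attr(
        stats::predict(m, x[1, , drop = FALSE], decision.values = TRUE),
        "decision.values"))[1L], "1")
      list(score = function(nx) {
        dv <- as.numeric(attr(stats::predict(m, nx, decision.values = TRUE),
                              "decision.values"))
        if (pos_first) dv else -dv
      }, model = m)
    },
    gradient_boosting = {
      m <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3L,
                      eta = 0.1, tree_method = "exact", nthread = 1L),
        data = xgboost::xgb.DMatrix(x, label = y), nrounds = 100L)
      list(score = function(nx) {
        as.numeric(stats::predict(m, xgboost::xgb.DMatrix(nx)))
      }, model = m)
    },
    xgboost = {
      m <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", tree_method = "exact",
                      nthread = 1L),
        data = xgboost::xgb.DMatrix(x, label = y), nrounds = 100L)
      list(score = function(nx) {
        as.numeric(stats::predict(m, xgboost::xgb.DMatrix(nx)))
      }, model = m)
    },
    k_nearest_neighbors = {
      list(score = function(nx) {
        pred <- class::knn(x, nx, yf, k = 5L, prob = TRUE)
        p <- attr(pred, "prob")
        ifelse(pred == "1", p, 1 - p)
      })
    }
  ))
  structure(list(name = name, label = classifier_label(name),
                 score = fit$score, model = fit$model, seed = seed),
            class = "fd_classifier")
}

#' Score and classify with a fitted classifier
#'
#' @param clf an `fd_classifier`.
#' @param newx standardized feature matrix.
#' @param threshold score cut for the positive class.
#' @return List with `score` and `class` (0/1).
#' @export
predict_classifier <- function(clf, newx, threshold = 0.5) {
  if (!inherits(clf, "fd_classifier")) stop("not an fd_classifier", call. = FALSE)
  s <- clf$score(newx)
  cl <- as.integer(if (clf$name == "support_vector_machine") s > 0 else
                   s > threshold)
  list(score = s, class = cl)
}

#' Confusion matrix from labels and predictions
#'
#' @param truth,predicted 0/1 integer vectors; 1 is the positive class.
#' @return List of class `confusion_matrix` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 tn = sum(truth == 0L & predicted == 0L),
                 fp = sum(truth == 0L & predicted == 1L),
                 fn = sum(truth == 1L & predicted == 0L)),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' `accuracy = (tp + tn) / total`, `precision = tp / (tp + fp)`,
#' `recall = tp / (tp + fn)`, `f1 = 2 p r / (p + r)`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never silently 0.
#'
#' @param cm a [confusion_matrix()] or list with `tp`, `tn`, `fp`, `fn`.
#' @return List with `accuracy`, `precision`, `recall`, `f1`.
#' @export
#' @examples
#' metrics_from_confusion(list(tp = 49, tn = 35, fp = 5, fn = 5))
metrics_from_confusion <- function(cm) {
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  total <- tp + tn + fp + fn
  if (total <= 0L) stop("empty confusion matrix", call. = FALSE)
  if (any(c(tp, tn, fp, fn) < 0L)) stop("negative counts", call. = FALSE)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' ROC curve points
#'
#' One point per distinct score threshold, plus the (0, 0) and (1, 1)
#' endpoints; the false-positive-rate grid is monotone non-decreasing.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 truth labels containing both classes.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nn,
                numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under the ROC curve
#'
#' @inheritParams roc_points
#' @return Scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Precision-recall curve points
#'
#' @inheritParams roc_points
#' @return Data frame with columns `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(scores, labels) {
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  np <- sum(labels == 1L)
  thr <- sort(unique(scores), decreasing = TRUE)
  rows <- lapply(thr, function(t) {
    sel <- scores >= t
    data.frame(threshold = t,
               recall = sum(sel & labels == 1L) / np,
               precision = sum(labels[sel] == 1L) / sum(sel))
  })
  do.call(rbind, rows)
}

# Stratified k-fold assignment: within each class, shuffled indices are
# dealt round-robin so every fold holds both classes.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of one classifier family
#'
#' Per-fold accuracy, precision, recall, F1 and ROC-AUC over all rows of
#' the feature matrix, with mean and SD across folds.
#'
#' @param name one of [classifier_names()].
#' @param features an `fd_features` object.
#' @param k number of folds (>= 2).
#' @param seed RNG seed for fold assignment and stochastic fits.
#' @return List of class `cv_report`: `model`, `folds` (per-fold data
#'   frame), `mean`, `sd`.
#' @export
cross_validate <- function(name, features, k = 5L, seed = 42L) {
  if (!inherits(features, "fd_features"))
    stop("features must come from build_features()", call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  fold <- stratified_folds(features$y, k, seed)
  if (any(tapply(features$y, fold, function(v) length(unique(v))) < 2L))
    stop("a fold lost one class: use stratification or a larger cohort",
         call. = FALSE)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    clf <- fit_classifier(name, features$x[tr, , drop = FALSE],
                          features$y[tr], seed = seed)
    pred <- predict_classifier(clf, features$x[!tr, , drop = FALSE])
    met <- metrics_from_confusion(confusion_matrix(features$y[!tr],
                                                   pred$class))
    data.frame(fold = f, accuracy = met$accuracy, precision = met$precision,
               recall = met$recall, f1 = met$f1,
               roc_auc = roc_auc(pred$score, features$y[!tr]))
  })
  folds <- do.call(rbind, per_fold)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "roc_auc")
  structure(list(model = name, label = classifier_label(name), folds = folds,
                 mean = colMeans(folds[metric_cols]),
                 sd = apply(folds[metric_cols], 2L, stats::sd)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s (%d-fold CV)\n", x$label, nrow(x$folds)))
  for (m in names(x$mean))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Run the full six-classifier benchmark
#'
#' Cross-validates every family of [classifier_names()], ranks by mean CV
#' accuracy (ties by mean ROC-AUC), and evaluates each family fitted on
#' the training partition against the validation and test partitions,
#' reporting the test confusion matrix under both the patient-positive
#' and control-positive conventions.
#'
#' @param features an `fd_features` object.
#' @param k CV folds.
#' @param seed RNG seed.
#' @return List of class `fd_benchmark`: `cv` (metrics table, one row per
#'   model with mean/SD columns and rank), `reports` (per-model
#'   `cv_report`s), `holdout` (per-model validation/test metrics and test
#'   confusion matrix).
#' @export
benchmark_classifiers <- function(features, k = 5L, seed = 42L) {
  reports <- lapply(classifier_names(), cross_validate,
                    features = features, k = k, seed = seed)
  names(reports) <- classifier_names()
  cv <- do.call(rbind, lapply(reports, function(r) {
    data.frame(model = r$label,
               accuracy = r$mean[["accuracy"]], accuracy_sd = r$sd[["accuracy"]],
               precision = r$mean[["precision"]], precision_sd = r$sd[["precision"]],
               recall = r$mean[["recall"]], recall_sd = r$sd[["recall"]],
               f1 = r$mean[["f1"]], f1_sd = r$sd[["f1"]],
               roc_auc = r$mean[["roc_auc"]], roc_auc_sd = r$sd[["roc_auc"]])
  }))
  cv$rank <- rank(-(cv$accuracy + 1e-9 * cv$roc_auc), ties.method = "first")
  cv <- cv[order(cv$rank), ]
  rownames(cv) <- NULL
  tr <- features$partition == "train"
  holdout <- lapply(classifier_names(), function(nm) {
    clf <- fit_classifier(nm, features$x[tr, , drop = FALSE], features$y[tr],
                          seed = seed)
    eval_part <- function(p) {
      sel <- features$partition == p
      pred <- predict_classifier(clf, features$x[sel, , drop = FALSE])
      cmx <- confusion_matrix(features$y[sel], pred$class)
      c(metrics_from_confusion(cmx),
        list(roc_auc = roc_auc(pred$score, features$y[sel]), confusion = cmx))
    }
    val <- eval_part("validation"); tst <- eval_part("test")
    flipped <- list(tp = tst$confusion$tn, tn = tst$confusion$tp,
                    fp = tst$confusion$fn, fn = tst$confusion$fp)
    list(model = nm, validation = val, test = tst,
         test_control_positive = metrics_from_confusion(flipped))
  })
  names(holdout) <- classifier_names()
  structure(list(cv = cv, reports = reports, holdout = holdout,
                 seed = seed, k = k), class = "fd_benchmark")
}

#' @export
print.fd_benchmark <- function(x, ...) {
  cat(sprintf("Six-classifier benchmark (%d-fold CV, seed %d)\n", x$k, x$seed))
  tab <- x$cv
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %d. %-22s acc %.2f+/-%.2f  F1 %.2f+/-%.2f  AUC %.2f+/-%.2f\n",
                tab$rank[i], tab$model[i], tab$accuracy[i], tab$accuracy_sd[i],
                tab$f1[i], tab$f1_sd[i], tab$roc_auc[i], tab$roc_auc_sd[i]))
  invisible(x)
}

#' Split-gain feature importance of a fitted tree ensemble
#'
#' Normalized to sum 1 and sorted descending. Supported for the random
#' forest and the two boosted-tree families; other families raise an
#' error.
#'
#' @param clf an `fd_classifier`.
#' @param feature_names column names of the feature matrix.
#' @return Data frame with columns `feature`, `importance`.
#' @export
feature_importance <- function(clf,
                               feature_names = c("age", "gender",
                                                 "lc_fd", "rc_fd")) {
  if (!inherits(clf, "fd_classifier")) stop("not an fd_classifier", call. = FALSE)
  imp <- switch(clf$name,
    random_forest = {
      v <- randomForest::importance(clf$model)[, 1L]
      stats::setNames(as.numeric(v), rownames(randomForest::importance(clf$model)))
    },
    gradient_boosting = ,
    xgboost = {
      tab <- xgboost::xgb.importance(model = clf$model)
      stats::setNames(tab$Gain, tab$Feature)
    },
    stop("feature importance is unsupported for model '", clf$name,
         "': no split-gain importances", call. = FALSE)
  )
  full <- stats::setNames(rep(0, length(feature_names)), feature_names)
  full[names(imp)] <- imp
  if (sum(full) > 0) full <- full / sum(full)
  out <- data.frame(feature = names(full), importance = as.numeric(full))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}
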