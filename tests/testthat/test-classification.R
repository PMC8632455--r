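test_that("stratified splits preserve class counts and determinism", {
  lab <- rep(c("HQ", "LQ"), each = 50)
  sp <- split_train_test(lab, seed = 4)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_equal(sum(lab[sp$train] == "HQ"), 40)
  expect_equal(sum(lab[sp$test] == "LQ"), 10)
  expect_identical(split_train_test(lab, seed = 4), sp)
  expect_false(identical(split_train_test(lab, seed = 5)$train, sp$train))
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("explicit per-class train counts override the 4:1 ratio", {
  lab <- rep(c("HQ", "LQ"), each = 75)
  sp <- split_train_test(lab, seed = 1, n_train_per_class = 50)
  expect_equal(sum(lab[sp$train] == "HQ"), 50)
  expect_equal(sum(lab[sp$train] == "LQ"), 50)
  expect_equal(sum(lab[sp$test] == "HQ"), 25)
  expect_equal(sum(lab[sp$test] == "LQ"), 25)
  expect_error(split_train_test(rep(c("a", "b"), c(4, 50))), "at least 5")
})

test_that("confusion report reproduces hand-derived metrics", {
  # counts tp=9, fn=1, fp=2, tn=8 for a 20-sample toy problem
  y_true <- c(rep("pos", 10), rep("neg", 10))
  y_pred <- c(rep("pos", 9), "neg", rep("neg", 8), "pos", "pos")
  out <- confusion_and_report(y_true, y_pred, positive = "pos")
  expect_equal(unname(out$confusion), c(9, 1, 2, 8))
  expect_equal(out$report$precision[1], 9 / 11)
  expect_equal(out$report$sensitivity[1], 9 / 10)
  f1 <- 2 * (9 / 11) * (9 / 10) / (9 / 11 + 9 / 10)
  expect_equal(out$report$f1[1], f1)
  # negative-class row swaps the positive designation
  expect_equal(out$report$precision[2], 8 / 9)
  expect_equal(out$report$sensitivity[2], 8 / 10)
  expect_equal(out$accuracy, 17 / 20)
  # perfect prediction
  perf <- confusion_and_report(y_true, y_true, "pos")
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$report$f1, c(1, 1))
  # undefined metrics are NA with a warning, not zero
  w <- capture_warnings(
    und <- confusion_and_report(c("neg", "neg"), c("neg", "neg"), "pos"))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.na(und$report$precision[1]))
  expect_error(confusion_and_report(character(0), character(0), "pos"))
})

test_that("ROC AUC equals the pairwise-concordance oracle", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    y <- sample(c("pos", "neg"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    scores <- round(runif(n), sample(1:3, 1))  # rounding creates ties
    auc <- roc_curve_auc(y, scores, "pos")$auc
    pos <- scores[y == "pos"]; neg <- scores[y != "pos"]
    conc <- 0
    for (p in pos) for (q in neg)
      conc <- conc + (p > q) + 0.5 * (p == q)
    expect_equal(auc, conc / (length(pos) * length(neg)), tolerance = 1e-12)
  }
})

test_that("ROC endpoints behave under perfect and constant scores", {
  y <- c("pos", "pos", "neg", "neg")
  expect_equal(roc_curve_auc(y, c(0.9, 0.8, 0.2, 0.1), "pos")$auc, 1)
  expect_equal(roc_curve_auc(y, rep(0.5, 4), "pos")$auc, 0.5)
  expect_error(roc_curve_auc(c("pos", "pos"), c(0.1, 0.2), "pos"),
               "both classes")
})

test_that("training is reproducible and refuses degenerate inputs", {
  set <- generate_dataset(separable_config(6, seed = 3), "blastocyst")
  pp <- preprocess_set(set)
  lab <- task_labels(set, "blastocyst")
  cfg <- ann_config(seed = 7, max_epochs = 5)
  m1 <- train_ann(pp$X, lab, cfg, "HQ")
  m2 <- train_ann(pp$X, lab, cfg, "HQ")
  expect_equal(tail(m1$training_history, 1), tail(m2$training_history, 1),
               tolerance = 1e-10)
  expect_true(all(is.finite(m1$training_history)))
  expect_error(train_ann(pp$X[lab == "HQ", ], lab[lab == "HQ"], cfg),
               "2 classes")
  expect_error(predict_proba(m1, pp$X[, 1:100]), "width")
  P <- predict_proba(m1, pp$X)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(P[1, ], predict_proba(m1, pp$X[c(1, 1), ])[2, ])
})

test_that("a separable cohort is classified perfectly on holdout", {
  set <- generate_dataset(separable_config(15, seed = 5), "blastocyst")
  pp <- preprocess_set(set, denoise = "db4")
  lab <- task_labels(set, "blastocyst")
  sp <- split_train_test(lab, seed = 3)
  model <- train_ann(pp$X[sp$train, ], lab[sp$train], ann_config(seed = 4),
                     "HQ")
  pred <- predict_class(model, pp$X[sp$test, ])
  expect_equal(mean(pred == lab[sp$test]), 1)
  # probabilities argmax equals the label on every test sample
  P <- predict_proba(model, pp$X[sp$test, ])
  expect_equal(model$classes[max.col(P)], lab[sp$test])
})

test_that("label permutation drives holdout accuracy to chance", {
  cfg <- synthetic_config(n_per_group = 25, replicates = 2, seed = 19,
                          effects = list(group_effect("LQ", ZONE_A, 1.3)))
  set <- generate_dataset(cfg, "blastocyst")
  pp <- preprocess_set(set, denoise = "db4")
  lab <- task_labels(set, "blastocyst")
  set.seed(8)
  perm <- sample(lab)
  sp <- split_train_test(perm, seed = 3)
  model <- train_ann(pp$X[sp$train, ], perm[sp$train],
                     ann_config(seed = 4, max_epochs = 150), "HQ")
  acc <- mean(predict_class(model, pp$X[sp$test, ]) == perm[sp$test])
  n_test <- length(sp$test)
  band <- 1.96 * sqrt(0.25 / n_test)
  expect_gte(acc, 0.5 - band)
  expect_lte(acc, 0.5 + band)
})

test_that("five-fold CV is perfect on separable data and reports 5 folds", {
  set <- generate_dataset(separable_config(10, seed = 6), "blastocyst")
  pp <- preprocess_set(set)
  lab <- task_labels(set, "blastocyst")
  cv <- five_fold_cv(pp$X, lab, ann_config(seed = 2, max_epochs = 200), "HQ",
                     seed = 9)
  expect_equal(cv$n_folds, 5)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(cv$auc_mean, 1)
  expect_equal(cv$auc_sd, 0)
  mix <- c(1:3, 11:13)  # 3 per class
  expect_error(five_fold_cv(pp$X[mix, ], lab[mix], ann_config(), "HQ"),
               "at least 5")
})

test_that("LOOCV predicts every sample once and aces separable data", {
  set <- generate_dataset(separable_config(5, seed = 7), "blastocyst")
  pp <- preprocess_set(set)
  lab <- task_labels(set, "blastocyst")
  lo <- loocv(pp$X, lab, ann_config(seed = 3, max_epochs = 120), "HQ")
  expect_equal(nrow(lo$predictions), 10)
  expect_equal(lo$accuracy, 1)
  mix <- c(1:2, 6:7)  # 2 per class
  expect_error(loocv(pp$X[mix, ], lab[mix], ann_config(), "HQ"), "at least 3")
})

test_that("pregnancy rates per stratum round to whole percentages", {
  meta <- data.frame(
    blastocyst = rep(c("HQ", "LQ"), c(75, 75)),
    pregnancy = c(rep("success", 62), rep("failure", 13),
                  rep("success", 23), rep("failure", 52)))
  out <- pregnancy_rate_summary(meta)
  expect_equal(out$rate_percent[out$blastocyst == "HQ"], 83)
  expect_equal(out$rate_percent[out$blastocyst == "LQ"], 31)
  expect_equal(out$n, c(75, 75))
  zero <- pregnancy_rate_summary(
    data.frame(blastocyst = rep("HQ", 10), pregnancy = rep("failure", 10)))
  expect_equal(zero$rate_percent, 0)
})
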