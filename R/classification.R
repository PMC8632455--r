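#' Stratified train/test split by sample
#'
#' Splits samples (one row per biological sample; replicates were
#' averaged upstream, so replicate spectra can never straddle the
#' split) at a 4:1 train:test ratio by default, stratified by label and
#' deterministic given `seed`. An explicit per-class training count may
#' replace the ratio.
#'
#' @param labels per-sample class labels.
#' @param ratio training fraction (default 0.8).
#' @param seed RNG seed.
#' @param n_train_per_class optional fixed number of training samples
#'   per class (overrides `ratio`).
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, ratio = 0.8, seed = 1L,
                             n_train_per_class = NULL) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 5)) stop("each class needs at least 5 samples to split")
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    n_tr <- if (is.null(n_train_per_class)) round(ratio * length(idx))
            else n_train_per_class
    if (n_tr < 1 || n_tr >= length(idx))
      stop("training count leaves no test samples for class ", cl)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Confusion matrix and per-class performance report
#'
#' Counts tp/fn/fp/tn for the designated positive class and derives
#' precision `tp/(tp+fp)`, sensitivity `tp/(tp+fn)`, F1 (harmonic mean
#' of the two) for both classes (the negative class report swaps the
#' positive designation), plus overall accuracy. Undefined 0/0 metrics
#' are reported as `NA` with a warning.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive label of the positive class.
#' @return list with `confusion` (tp, fn, fp, tn), `report` (data.frame
#'   with one row per class: precision, sensitivity, f1) and `accuracy`.
#' @export
confusion_and_report <- function(y_true, y_pred, positive) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (!length(y_true) || length(y_true) != length(y_pred))
    stop("y_true and y_pred must be non-empty and of equal length")
  classes <- c(positive, setdiff(sort(unique(c(y_true, y_pred))), positive))
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  metric <- function(num, den, name, cl) {
    if (den == 0) {
      warning(name, " undefined (0/0) for class ", cl)
      return(NA_real_)
    }
    num / den
  }
  one_class <- function(tp, fn, fp, cl) {
    prec <- metric(tp, tp + fp, "precision", cl)
    sens <- metric(tp, tp + fn, "sensitivity", cl)
    f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    data.frame(class = cl, precision = prec, sensitivity = sens, f1 = f1,
               stringsAsFactors = FALSE)
  }
  report <- rbind(one_class(tp, fn, fp, classes[1]),
                  one_class(tn, fp, fn, classes[2]))
  list(confusion = c(tp = tp, fn = fn, fp = fp, tn = tn),
       report = report,
       accuracy = (tp + tn) / length(y_true))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique positive-class scores,
#' records (FPR, TPR) points, and integrates by trapezoid. With ties
#' handled by the sweep, the AUC equals the Mann-Whitney pairwise
#' concordance statistic (ties counted 1/2).
#'
#' @param y_true label vector containing both classes.
#' @param scores positive-class probabilities or scores.
#' @param positive label of the positive class.
#' @return list with `curve` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
roc_curve_auc <- function(y_true, scores, positive) {
  y <- as.character(y_true) == positive
  if (all(y) || !any(y)) stop("y_true must contain both classes")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / sum(y), numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / sum(!y), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Stratified five-fold cross-validation of the classifier
#'
#' Assigns samples to 5 stratified folds (deterministic given `seed`),
#' trains on four folds and evaluates on the fifth in turn. Reports
#' per-fold AUC plus sensitivity and specificity at the 0.5 probability
#' threshold, summarized as mean and SD across folds.
#'
#' @param X samples-by-feature matrix.
#' @param labels per-sample class labels.
#' @param config an [ann_config()].
#' @param positive positive-class label.
#' @param seed RNG seed for fold assignment (per-fold training seeds are
#'   derived from it).
#' @param n_folds number of folds (default 5).
#' @return list of class `cv_summary`: `auc_mean`, `auc_sd`,
#'   `sens_mean`, `sens_sd`, `spec_mean`, `spec_sd`, `n_folds`,
#'   `per_fold` (data.frame).
#' @export
five_fold_cv <- function(X, labels, config = ann_config(), positive,
                         seed = 1L, n_folds = 5L) {
  labels <- as.character(labels)
  if (any(table(labels) < n_folds))
    stop("each class needs at least ", n_folds, " samples")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  rows <- lapply(seq_len(n_folds), function(k) {
    tr <- fold != k; te <- !tr
    cfg <- config; cfg$seed <- config$seed + k
    model <- train_ann(X[tr, , drop = FALSE], labels[tr], cfg, positive)
    P <- predict_proba(model, X[te, , drop = FALSE])
    pred <- model$classes[ifelse(P[, 1] >= 0.5, 1L, 2L)]
    y <- labels[te]
    roc <- roc_curve_auc(y, P[, 1], positive)
    data.frame(fold = k, auc = roc$auc,
               sensitivity = sum(pred == positive & y == positive) /
                 sum(y == positive),
               specificity = sum(pred != positive & y != positive) /
                 sum(y != positive))
  })
  per_fold <- do.call(rbind, rows)
  structure(list(auc_mean = mean(per_fold$auc), auc_sd = stats::sd(per_fold$auc),
                 sens_mean = mean(per_fold$sensitivity),
                 sens_sd = stats::sd(per_fold$sensitivity),
                 spec_mean = mean(per_fold$specificity),
                 spec_sd = stats::sd(per_fold$specificity),
                 n_folds = n_folds, per_fold = per_fold),
            class = "cv_summary")
}

#' Leave-one-out cross-validation of the classifier
#'
#' Trains on all samples but one and predicts the held-out sample, for
#' every sample in turn.
#'
#' @inheritParams five_fold_cv
#' @return list with `predictions` (data.frame: sample, true, predicted,
#'   prob_positive) and `accuracy`.
#' @export
loocv <- function(X, labels, config = ann_config(), positive) {
  labels <- as.character(labels)
  if (any(table(labels) < 3)) stop("each class needs at least 3 samples")
  n <- nrow(X)
  rows <- lapply(seq_len(n), function(i) {
    cfg <- config; cfg$seed <- config$seed + i
    model <- train_ann(X[-i, , drop = FALSE], labels[-i], cfg, positive)
    P <- predict_proba(model, X[i, , drop = FALSE])
    data.frame(sample = i, true = labels[i],
               predicted = model$classes[if (P[1, 1] >= 0.5) 1L else 2L],
               prob_positive = P[1, 1], stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, rows)
  list(predictions = preds, accuracy = mean(preds$predicted == preds$true))
}

#' Clinical pregnancy rate by blastocyst-quality stratum
#'
#' Counts pregnancy successes within each blastocyst-quality stratum and
#' reports the rate as a percentage rounded to the nearest integer
#' (e.g. 62 successes of 75 high-quality transfers -> 83%).
#'
#' @param meta data.frame with `blastocyst` and `pregnancy` columns (no
#'   missing values among the included samples).
#' @return data.frame with one row per stratum: `blastocyst`, `n`,
#'   `successes`, `rate_percent`.
#' @export
pregnancy_rate_summary <- function(meta) {
  stopifnot(all(c("blastocyst", "pregnancy") %in% names(meta)))
  keep <- !is.na(meta$blastocyst) & !is.na(meta$pregnancy)
  meta <- meta[keep, ]
  strata <- sort(unique(meta$blastocyst))
  rows <- lapply(strata, function(s) {
    n <- sum(meta$blastocyst == s)
    succ <- sum(meta$blastocyst == s & meta$pregnancy == "success")
    rate <- if (n == 0) { warning("empty stratum ", s); NA_real_ }
            else round(100 * succ / n)
    data.frame(blastocyst = s, n = n, successes = succ, rate_percent = rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
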