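#' Assemble an end-to-end pipeline configuration
#'
#' A single seed here drives every stochastic stage (generation, splits,
#' training); two runs with an identical configuration produce identical
#' outputs.
#'
#' @param task `"pcos"`, `"blastocyst"` or `"pregnancy"`.
#' @param manifest path to a dataset manifest, or `NULL` to generate a
#'   synthetic cohort from `synthetic`.
#' @param synthetic a [synthetic_config()] (used when `manifest` is
#'   `NULL`).
#' @param fingerprint analysis zone (default `c(600, 1800)`).
#' @param denoise `FALSE`, `"db4"` or `"haar"` (classification path).
#' @param min_width,max_zones zone-scan parameters.
#' @param min_prominence loading-extrema prominence fraction.
#' @param ann an [ann_config()].
#' @param mode evaluation protocol: `"holdout"`, `"cv5"` or `"loocv"`.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(task = "pcos", manifest = NULL,
                            synthetic = synthetic_config(),
                            fingerprint = c(600, 1800), denoise = "db4",
                            min_width = 30, max_zones = 2,
                            min_prominence = 0.2,
                            ann = ann_config(),
                            mode = c("holdout", "cv5", "loocv"),
                            seed = 1L) {
  structure(list(task = task, manifest = manifest, synthetic = synthetic,
                 fingerprint = fingerprint, denoise = denoise,
                 min_width = min_width, max_zones = max_zones,
                 min_prominence = min_prominence, ann = ann,
                 mode = match.arg(mode), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass_deep(config), f, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

pipeline_dataset <- function(config) {
  if (!is.null(config$manifest)) return(read_dataset_manifest(config$manifest))
  syn <- config$synthetic
  syn$seed <- config$seed
  generate_dataset(syn, config$task)
}

#' Run the discovery arm of the pipeline
#'
#' Loads or generates the cohort, preprocesses it (crop + vector
#' normalization, replicate averaging; no denoising on the discovery
#' path), and emits group mean spectra with SDs, mean-centered group
#' differences, PCA scores/loadings/explained variance, loading-anchored
#' zone scanning with Welch statistics, and per-sample quantifications.
#' When `out_dir` is given, writes `report.json` and
#' `quantifications.csv`, each carrying the config hash.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return the discovery report, invisibly a list.
#' @export
run_discovery <- function(config, out_dir = NULL) {
  set_ <- pipeline_dataset(config)
  labels <- task_labels(set_, config$task)
  positive <- task_positive_class(config$task)
  pp <- preprocess_set(set_, fingerprint = config$fingerprint)
  X <- pp$X; wn <- pp$wavenumber
  mc <- mean_center(X, labels)
  pca <- pca_decompose(X, n_components = 2, wavenumber = wn)
  anchors <- loading_extrema(pca, 1, config$min_prominence)
  scan <- if (length(anchors) >= 2)
    scan_zones(X, labels, anchors, wn, positive,
               config$min_width, config$max_zones)
  else { warning("fewer than 2 loading anchors; zone scan skipped"); NULL }
  zones <- if (!is.null(scan) && nrow(scan))
    lapply(seq_len(nrow(scan)), function(i) c(scan$zone_lo[i], scan$zone_hi[i]))
  else list()
  report <- if (length(zones))
    group_difference_report(X, labels, zones, wn, positive) else NULL
  group_mean <- do.call(rbind, lapply(split(seq_len(nrow(X)), labels),
                                      function(i) colMeans(X[i, , drop = FALSE])))
  group_sd <- do.call(rbind, lapply(split(seq_len(nrow(X)), labels),
                                    function(i) apply(X[i, , drop = FALSE], 2, stats::sd)))
  out <- list(task = config$task, positive = positive,
              config_hash = config_hash(config),
              wavenumber = wn,
              group_mean = group_mean, group_sd = group_sd,
              mean_centered_group_means = mc$group_means,
              explained_variance_fraction = pca$explained_variance_fraction,
              loading_anchors = anchors,
              zone_stats = if (!is.null(scan)) scan else NULL,
              report = report,
              provenance = pp$provenance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    json <- out
    json$wavenumber <- NULL; json$group_mean <- NULL; json$group_sd <- NULL
    json$mean_centered_group_means <- NULL
    json$report <- NULL
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    if (!is.null(report))
      utils::write.csv(cbind(config_hash = out$config_hash,
                             report$quantifications),
                       file.path(out_dir, "quantifications.csv"),
                       row.names = FALSE)
  }
  invisible(out)
}

#' Run the classification arm of the pipeline
#'
#' Loads or generates the cohort, preprocesses it for classification
#' (crop, vector normalization, wavelet denoising, replicate averaging),
#' then evaluates the fully connected classifier under the configured
#' protocol: a stratified 4:1 holdout (confusion matrix + per-class
#' report + ROC), five-fold cross-validation (AUC/sensitivity/
#' specificity mean +/- SD), or leave-one-out. When `out_dir` is given,
#' writes `metrics.json` carrying the config hash.
#'
#' @inheritParams run_discovery
#' @return the metrics report, invisibly a list.
#' @export
run_classification <- function(config, out_dir = NULL) {
  set_ <- pipeline_dataset(config)
  labels <- task_labels(set_, config$task)
  positive <- task_positive_class(config$task)
  pp <- preprocess_set(set_, fingerprint = config$fingerprint,
                       denoise = config$denoise)
  X <- pp$X
  ann <- config$ann
  ann$seed <- config$seed
  out <- list(task = config$task, positive = positive, mode = config$mode,
              config_hash = config_hash(config),
              ann_config = unclass(ann), provenance = pp$provenance)
  if (config$mode == "holdout") {
    sp <- split_train_test(labels, seed = config$seed)
    model <- train_ann(X[sp$train, , drop = FALSE], labels[sp$train],
                       ann, positive)
    P <- predict_proba(model, X[sp$test, , drop = FALSE])
    pred <- model$classes[ifelse(P[, 1] >= 0.5, 1L, 2L)]
    cr <- confusion_and_report(labels[sp$test], pred, positive)
    roc <- roc_curve_auc(labels[sp$test], P[, 1], positive)
    out$confusion <- as.list(cr$confusion)
    out$report <- cr$report
    out$accuracy <- cr$accuracy
    out$auc <- roc$auc
    out$roc_points <- roc$curve
  } else if (config$mode == "cv5") {
    cv <- five_fold_cv(X, labels, ann, positive, seed = config$seed)
    out$cv_summary <- unclass(cv)
  } else {
    lo <- loocv(X, labels, ann, positive)
    out$loocv_accuracy <- lo$accuracy
    out$predictions <- lo$predictions
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(out, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  invisible(out)
}
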