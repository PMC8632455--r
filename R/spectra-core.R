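#' Construct a single Raman spectrum
#'
#' A spectrum is an intensity trace on a uniform wavenumber grid
#' (Raman shift, cm^-1). The grid must be strictly ascending with a
#' constant step; the default acquisition range in this package is
#' 50--2000 cm^-1 at 1 cm^-1 resolution.
#'
#' @param wavenumber numeric vector of grid points (cm^-1), ascending,
#'   uniformly spaced.
#' @param intensity numeric vector of intensities, same length as
#'   `wavenumber`; all values must be finite.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber` and `intensity`.
#' @export
raman_spectrum <- function(wavenumber, intensity) {
  if (!is.numeric(wavenumber) || !is.numeric(intensity))
    stop("wavenumber and intensity must be numeric vectors")
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity must have equal length")
  if (length(wavenumber) < 2L)
    stop("a spectrum needs at least two grid points")
  if (!all(is.finite(wavenumber)))
    stop("non-finite wavenumber values")
  if (!all(is.finite(intensity)))
    stop("non-finite intensity values")
  steps <- diff(wavenumber)
  if (any(steps <= 0))
    stop("wavenumbers must be strictly ascending")
  if (max(steps) - min(steps) > 1e-6 * max(abs(steps)))
    stop("non-uniform wavenumber grid (step varies)")
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity)),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %g..%g cm^-1 (step %g)\n",
              length(x$wavenumber), x$wavenumber[1],
              x$wavenumber[length(x$wavenumber)], grid_step(x$wavenumber)))
  invisible(x)
}

# uniform step of an ascending grid
grid_step <- function(w) (w[length(w)] - w[1]) / (length(w) - 1)

#' Build a uniform wavenumber grid
#'
#' @param start,stop interval endpoints in cm^-1 (`start < stop`), both
#'   included in the grid.
#' @param step grid spacing in cm^-1 (default 1, the acquisition
#'   resolution).
#' @return numeric vector `start, start+step, ..., stop`.
#' @export
wavenumber_grid <- function(start = 50, stop = 2000, step = 1) {
  if (start >= stop) stop("start must be < stop")
  if (step <= 0) stop("step must be > 0")
  seq(start, stop, by = step)
}

#' Construct a labeled set of replicate spectra
#'
#' Container for a cohort: per-sample metadata (labels) and, for each
#' sample, one or more replicate spectra acquired at random spots of the
#' same fluid drop. All spectra share one wavenumber grid.
#'
#' @param meta data.frame with columns `sample_id` (unique), `group_pcos`
#'   (`"PCOS"`/`"nonPCOS"` or `NA`), `blastocyst` (`"HQ"`/`"LQ"` or `NA`),
#'   `pregnancy` (`"success"`/`"failure"` or `NA`). Missing label columns
#'   are filled with `NA`.
#' @param wavenumber shared grid (ascending, uniform).
#' @param spectra named list (names = `sample_id`) of replicate-by-
#'   wavenumber intensity matrices.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(meta, wavenumber, spectra) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("meta must contain sample_id")
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  for (col in c("group_pcos", "blastocyst", "pregnancy"))
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  if (!setequal(names(spectra), meta$sample_id))
    stop("spectra list names must match meta$sample_id")
  spectra <- spectra[meta$sample_id]
  # grid validation (reuse spectrum constructor checks)
  raman_spectrum(wavenumber, rep(0, length(wavenumber)))
  for (id in meta$sample_id) {
    m <- spectra[[id]]
    if (!is.matrix(m)) spectra[[id]] <- m <- matrix(m, nrow = 1)
    if (ncol(m) != length(wavenumber))
      stop("sample ", id, ": replicate length does not match the shared grid")
    if (nrow(m) < 1L) stop("sample ", id, " has no replicates")
    if (!all(is.finite(m))) stop("sample ", id, ": non-finite intensities")
  }
  structure(list(meta = meta, wavenumber = as.numeric(wavenumber),
                 spectra = spectra),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  reps <- vapply(x$spectra, nrow, integer(1))
  cat(sprintf("<spectrum_set> %d samples, %s replicates/sample, %d grid points (%g..%g cm^-1)\n",
              nrow(x$meta),
              if (length(unique(reps)) == 1L) as.character(reps[1])
              else paste0(min(reps), "-", max(reps)),
              length(x$wavenumber), x$wavenumber[1],
              x$wavenumber[length(x$wavenumber)]))
  invisible(x)
}

#' Number of samples in a spectrum set
#' @param set a `spectrum_set`.
#' @return integer count.
#' @export
n_samples <- function(set) nrow(set$meta)

#' Extract task labels from a spectrum set
#'
#' @param set a `spectrum_set`.
#' @param task one of `"pcos"`, `"blastocyst"`, `"pregnancy"`.
#' @return character vector of per-sample labels (may contain `NA`).
#' @export
task_labels <- function(set, task = c("pcos", "blastocyst", "pregnancy")) {
  task <- match.arg(task)
  col <- switch(task, pcos = "group_pcos", blastocyst = "blastocyst",
                pregnancy = "pregnancy")
  set$meta[[col]]
}

#' Positive class label for a task
#'
#' The class treated as "positive" in confusion matrices and ROC curves:
#' PCOS for the PCOS task, HQ for blastocyst quality, success for
#' pregnancy outcome.
#'
#' @inheritParams task_labels
#' @return single character label.
#' @export
task_positive_class <- function(task = c("pcos", "blastocyst", "pregnancy")) {
  switch(match.arg(task), pcos = "PCOS", blastocyst = "HQ",
         pregnancy = "success")
}

#' Subset a spectrum set by sample
#' @param set a `spectrum_set`.
#' @param idx integer or logical index into the samples, or character
#'   sample ids.
#' @return a `spectrum_set` with the selected samples.
#' @export
subset_samples <- function(set, idx) {
  if (is.character(idx)) idx <- match(idx, set$meta$sample_id)
  spectrum_set(set$meta[idx, , drop = FALSE], set$wavenumber,
               set$spectra[set$meta$sample_id[idx]])
}

#' Average the replicate spectra of each sample
#'
#' Collapses each sample to the pointwise mean of its replicates, giving
#' one spectrum per biological sample. This is the default reduction
#' before zone statistics (one quantification per sample) and before
#' classification (prevents replicate leakage across data splits).
#'
#' @param set a `spectrum_set`.
#' @return a `spectrum_set` with one replicate per sample.
#' @export
average_replicates <- function(set) {
  spectra <- lapply(set$spectra, function(m) matrix(colMeans(m), nrow = 1))
  spectrum_set(set$meta, set$wavenumber, spectra)
}

#' Stack a spectrum set into a samples-by-wavenumber matrix
#'
#' Requires one replicate per sample (run [average_replicates()] first
#' for multi-replicate sets).
#'
#' @param set a `spectrum_set` with one replicate per sample.
#' @return numeric matrix with rownames = sample ids.
#' @export
set_matrix <- function(set) {
  reps <- vapply(set$spectra, nrow, integer(1))
  if (any(reps != 1L))
    stop("set has multiple replicates per sample; call average_replicates() first")
  X <- do.call(rbind, set$spectra)
  rownames(X) <- set$meta$sample_id
  X
}

#' Read a spectrum from a two-column CSV file
#'
#' Expects columns wavenumber, intensity (header optional), ascending
#' wavenumbers on a uniform grid.
#'
#' @param path file path.
#' @return a `raman_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- suppressWarnings(is.na(as.numeric(first[1])))
  data_lines <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  w <- numeric(length(parts)); y <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L)
      stop("malformed row at line ", i + offset, " of ", path)
    vals <- suppressWarnings(as.numeric(p[1:2]))
    if (any(is.na(vals)))
      stop("non-numeric row at line ", i + offset, " of ", path)
    w[i] <- vals[1]; y[i] <- vals[2]
  }
  raman_spectrum(w, y)
}

#' Write a spectrum to a two-column CSV file
#'
#' Writes header `wavenumber_cm-1,intensity` and full double precision
#' so that a read/write round trip is exact.
#'
#' @param spectrum a `raman_spectrum`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (!all(is.finite(spectrum$intensity)))
    stop("spectrum has non-finite intensities; refusing to write")
  lines <- c("wavenumber_cm-1,intensity",
             paste(format(spectrum$wavenumber, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   format(spectrum$intensity, digits = 17, trim = TRUE),
                   sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Read a labeled dataset from a manifest file
#'
#' The manifest maps sample ids and labels to replicate spectrum files.
#' CSV manifests have columns `sample_id, group_pcos, blastocyst,
#' pregnancy, replicate_paths` (semicolon-separated paths); JSON
#' manifests are an array of objects with the same fields
#' (`replicate_paths` as an array). Paths are resolved relative to the
#' manifest's directory.
#'
#' @param path manifest file (`.csv` or `.json`).
#' @return a `spectrum_set`.
#' @export
read_dataset_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  dir <- dirname(path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    rows$replicate_paths <- vapply(rows$replicate_paths,
                                   function(p) paste(p, collapse = ";"),
                                   character(1))
  } else {
    rows <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  need <- c("sample_id", "replicate_paths")
  if (!all(need %in% names(rows)))
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  spectra <- list(); wn <- NULL
  for (i in seq_len(nrow(rows))) {
    files <- strsplit(rows$replicate_paths[i], ";", fixed = TRUE)[[1]]
    files <- trimws(files)
    mats <- vector("list", length(files))
    for (j in seq_along(files)) {
      f <- files[j]
      fp <- if (file.exists(f)) f else file.path(dir, f)
      if (!file.exists(fp))
        stop("replicate file not found: ", f, " (sample ", rows$sample_id[i], ")")
      sp <- read_spectrum_csv(fp)
      if (is.null(wn)) wn <- sp$wavenumber
      else if (length(sp$wavenumber) != length(wn) ||
               max(abs(sp$wavenumber - wn)) > 1e-9)
        stop("mixed wavenumber grids: ", f, " differs from first file")
      mats[[j]] <- sp$intensity
    }
    spectra[[rows$sample_id[i]]] <- do.call(rbind, mats)
  }
  meta <- rows[, setdiff(names(rows), "replicate_paths"), drop = FALSE]
  for (col in c("group_pcos", "blastocyst", "pregnancy"))
    if (col %in% names(meta)) meta[[col]][meta[[col]] %in% c("", "NA")] <- NA
  spectrum_set(meta, wn, spectra)
}

#' Write a dataset to spectrum CSVs plus a manifest
#'
#' Inverse of [read_dataset_manifest()]: one CSV per replicate under
#' `dir/spectra/`, a `manifest.csv`, and (optionally) a provenance JSON.
#'
#' @param set a `spectrum_set`.
#' @param dir output directory (created if needed).
#' @param provenance optional list serialized to `provenance.json`.
#' @return path to the manifest, invisibly.
#' @export
write_dataset <- function(set, dir, provenance = NULL) {
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  rows <- set$meta
  rows$replicate_paths <- vapply(rows$sample_id, function(id) {
    m <- set$spectra[[id]]
    files <- sprintf("spectra/%s_rep%d.csv", id, seq_len(nrow(m)))
    for (j in seq_len(nrow(m)))
      write_spectrum_csv(raman_spectrum(set$wavenumber, m[j, ]),
                         file.path(dir, files[j]))
    paste(files, collapse = ";")
  }, character(1))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(rows, manifest, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(provenance))
    jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
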