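#' Subtract a background spectrum
#'
#' Pointwise difference of a sample spectrum and its background control,
#' floored at zero (intensities are physically non-negative).
#'
#' @param spectrum,background `raman_spectrum`s on the same grid.
#' @return a `raman_spectrum`.
#' @export
subtract_background <- function(spectrum, background) {
  if (length(spectrum$wavenumber) != length(background$wavenumber) ||
      max(abs(spectrum$wavenumber - background$wavenumber)) > 1e-9)
    stop("spectrum and background are on different grids")
  raman_spectrum(spectrum$wavenumber,
                 pmax(spectrum$intensity - background$intensity, 0))
}

#' Crop a spectrum to a wavenumber zone
#'
#' Keeps the grid points with `lo <= w <= hi` (closed interval). The
#' default fingerprint region 600--1800 cm^-1 yields 1201 points on a
#' 1 cm^-1 grid.
#'
#' @param spectrum a `raman_spectrum`.
#' @param zone numeric `c(lo, hi)` in cm^-1; must lie within the grid.
#' @return a `raman_spectrum` on the restricted grid.
#' @export
crop_fingerprint <- function(spectrum, zone = c(600, 1800)) {
  w <- spectrum$wavenumber
  if (zone[1] < w[1] - 1e-9 || zone[2] > w[length(w)] + 1e-9)
    stop("zone [", zone[1], ", ", zone[2], "] outside the spectrum grid")
  keep <- w >= zone[1] - 1e-9 & w <= zone[2] + 1e-9
  raman_spectrum(w[keep], spectrum$intensity[keep])
}

#' Vector (L2) normalization
#'
#' Divides the intensities by their Euclidean norm so the spectrum has
#' unit length over its current grid. Applied over the fingerprint
#' region, this puts all samples on a common unitless intensity scale
#' (a flat 1201-point spectrum becomes 1/sqrt(1201) ~ 0.0289 everywhere).
#'
#' @param spectrum a `raman_spectrum`.
#' @return a unit-norm `raman_spectrum`.
#' @export
vector_normalize <- function(spectrum) {
  nrm <- sqrt(sum(spectrum$intensity^2))
  if (nrm <= 0) stop("cannot normalize an all-zero spectrum")
  raman_spectrum(spectrum$wavenumber, spectrum$intensity / nrm)
}

#' Wavelet-denoise a spectrum
#'
#' Applies [wavelet_denoise_vector()] to the intensities and then
#' re-normalizes to unit Euclidean norm, so denoised spectra stay on the
#' same unitless scale as their inputs.
#'
#' @param spectrum a vector-normalized `raman_spectrum`.
#' @param family `"db4"` (default) or `"haar"`.
#' @param level decomposition depth (default 4).
#' @return a denoised, unit-norm `raman_spectrum`.
#' @export
wavelet_denoise <- function(spectrum, family = c("db4", "haar"), level = 4) {
  y <- wavelet_denoise_vector(spectrum$intensity, family, level)
  vector_normalize(raman_spectrum(spectrum$wavenumber, y))
}

#' Mean-center a sample-by-wavenumber matrix
#'
#' Subtracts the grand mean spectrum (mean over all samples) from each
#' sample spectrum and, when group labels are supplied, returns the
#' per-group means of the centered spectra — the curves that display
#' between-group spectral contrast.
#'
#' @param X numeric matrix, samples in rows.
#' @param groups optional per-sample labels.
#' @return list with `centered` (matrix), `grand_mean` (vector) and,
#'   when `groups` is given, `group_means` (group-by-wavenumber matrix).
#' @export
mean_center <- function(X, groups = NULL) {
  if (nrow(X) < 2) stop("mean-centering needs at least 2 samples")
  gm <- colMeans(X)
  centered <- sweep(X, 2, gm)
  out <- list(centered = centered, grand_mean = gm)
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(X))
    out$group_means <- do.call(rbind, lapply(split(seq_len(nrow(X)), groups),
      function(i) colMeans(centered[i, , drop = FALSE])))
  }
  out
}

#' Preprocess a spectrum set for analysis
#'
#' The fixed pipeline: per-replicate background subtraction (when a
#' background is supplied), fingerprint cropping, vector normalization,
#' optional wavelet denoising (classification path only), replicate
#' averaging, and re-normalization of the per-sample mean spectrum.
#'
#' @param set a `spectrum_set`.
#' @param fingerprint analysis zone, default `c(600, 1800)`.
#' @param background optional background `raman_spectrum` on the
#'   acquisition grid.
#' @param denoise `FALSE` (default), `"db4"` or `"haar"`.
#' @param wavelet_level depth for denoising (default 4).
#' @return list with `X` (samples-by-wavenumber matrix of unit-norm
#'   spectra), `wavenumber`, `meta`, and `provenance` (ordered step
#'   record with parameters).
#' @export
preprocess_set <- function(set, fingerprint = c(600, 1800),
                           background = NULL, denoise = FALSE,
                           wavelet_level = 4) {
  steps <- character(0)
  proc <- lapply(set$meta$sample_id, function(id) {
    m <- set$spectra[[id]]
    reps <- lapply(seq_len(nrow(m)), function(r) {
      sp <- raman_spectrum(set$wavenumber, m[r, ])
      if (!is.null(background)) sp <- subtract_background(sp, background)
      sp <- vector_normalize(crop_fingerprint(sp, fingerprint))
      if (!isFALSE(denoise)) sp <- wavelet_denoise(sp, denoise, wavelet_level)
      sp$intensity
    })
    avg <- colMeans(do.call(rbind, reps))
    avg / sqrt(sum(avg^2))
  })
  X <- do.call(rbind, proc)
  rownames(X) <- set$meta$sample_id
  wn_full <- set$wavenumber
  wn <- wn_full[wn_full >= fingerprint[1] - 1e-9 &
                  wn_full <= fingerprint[2] + 1e-9]
  steps <- c(if (!is.null(background)) "subtract_background",
             sprintf("crop_fingerprint[%g,%g]", fingerprint[1], fingerprint[2]),
             "vector_normalize",
             if (!isFALSE(denoise))
               sprintf("wavelet_denoise(%s,level=%d)", denoise, wavelet_level),
             "average_replicates", "renormalize")
  list(X = X, wavenumber = wn, meta = set$meta,
       provenance = list(steps = steps))
}
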