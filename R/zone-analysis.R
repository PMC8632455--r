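#' Principal component analysis of preprocessed spectra
#'
#' Column-mean-centered PCA (no variance scaling; spectra share units)
#' of a samples-by-wavenumber matrix, with a deterministic sign
#' convention: every loading row is flipped so that its
#' largest-magnitude element is positive, and scores are flipped
#' accordingly.
#'
#' @param X numeric matrix, samples in rows, fingerprint grid in columns.
#' @param n_components number of components to retain.
#' @param wavenumber optional grid attached to the result (for
#'   [loading_extrema()]).
#' @return list of class `raman_pca` with `scores` (samples x
#'   components), `loadings` (components x wavenumbers, unit-norm rows),
#'   `explained_variance_fraction`, `center`, `wavenumber`.
#' @export
pca_decompose <- function(X, n_components = 2, wavenumber = NULL) {
  if (nrow(X) < 2) stop("PCA needs at least 2 samples")
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components > kmax)
    stop("n_components exceeds min(samples - 1, wavenumbers) = ", kmax)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- seq_len(n_components)
  loadings <- t(pc$rotation[, k, drop = FALSE])
  scores <- pc$x[, k, drop = FALSE]
  for (i in k) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) {
      loadings[i, ] <- -loadings[i, ]
      scores[, i] <- -scores[, i]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = ev[k] / sum(ev),
                 center = pc$center,
                 wavenumber = if (is.null(wavenumber)) as.numeric(colnames(X))
                              else wavenumber),
            class = "raman_pca")
}

#' Locate salient extrema of a PCA loading
#'
#' Local maxima of the absolute loading curve exceeding
#' `min_prominence` times the global maximum. These wavenumbers anchor
#' the candidate discriminative zones scanned by [scan_zones()].
#'
#' @param pca a `raman_pca`.
#' @param component which component's loading to scan (default 1).
#' @param min_prominence fraction of the global `max |loading|` a local
#'   maximum must reach (default 0.1).
#' @return sorted numeric vector of anchor wavenumbers (possibly empty).
#' @export
loading_extrema <- function(pca, component = 1, min_prominence = 0.1) {
  if (component > nrow(pca$loadings)) stop("component not present")
  v <- abs(pca$loadings[component, ])
  n <- length(v)
  if (max(v) == 0 || n < 3) return(numeric(0))
  # interior points strictly above the left neighbour and at least the
  # right one; a flat curve yields no anchors
  i <- 2:(n - 1)
  is_max <- logical(n)
  is_max[i] <- v[i] > v[i - 1] & v[i] >= v[i + 1] &
    v[i] >= min_prominence * max(v)
  sort(pca$wavenumber[is_max])
}

#' Width-averaged band integration over a zone
#'
#' Trapezoidal integral of the (vector-normalized) intensity over the
#' closed zone, divided by the zone width `hi - lo`. On this scale a
#' flat unit-norm 1201-point fingerprint spectrum quantifies to
#' 1/sqrt(1201) ~ 0.0289 in every zone.
#'
#' @param spectrum a `raman_spectrum` (normalized).
#' @param zone numeric `c(lo, hi)` within the grid.
#' @return single unitless quantification.
#' @export
quantify_zone <- function(spectrum, zone) {
  q <- quantify_zone_matrix(matrix(spectrum$intensity, nrow = 1),
                            spectrum$wavenumber, zone)
  as.numeric(q)
}

#' Zone quantification for a matrix of spectra
#'
#' @param X samples-by-wavenumber matrix.
#' @param wavenumber shared grid.
#' @param zone numeric `c(lo, hi)`.
#' @return numeric vector, one quantification per row of `X`.
#' @export
quantify_zone_matrix <- function(X, wavenumber, zone) {
  stopifnot(length(zone) == 2, zone[1] < zone[2])
  if (zone[1] < wavenumber[1] - 1e-9 ||
      zone[2] > wavenumber[length(wavenumber)] + 1e-9)
    stop("zone [", zone[1], ", ", zone[2], "] outside the analysis grid")
  keep <- which(wavenumber >= zone[1] - 1e-9 & wavenumber <= zone[2] + 1e-9)
  w <- wavenumber[keep]
  Y <- X[, keep, drop = FALSE]
  # trapezoid on a uniform grid: step * (sum - (first + last)/2)
  step <- grid_step(w)
  integral <- step * (rowSums(Y) - (Y[, 1] + Y[, ncol(Y)]) / 2)
  as.numeric(integral / (zone[2] - zone[1]))
}

#' Welch two-sample t test
#'
#' Mean-difference test without assuming equal group variances:
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value.
#' If both variances are zero the test degenerates: `p = 0` when the
#' means differ, `p = 1` otherwise.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t_stat`, `p_value`, `df`.
#' @export
welch_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (!is.finite(vx) || !is.finite(vy)) stop("non-finite variance")
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t_stat = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                p_value = if (same) 1 else 0,
                log_p = if (same) 0 else -Inf, df = NA_real_))
  }
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  # log-scale p survives underflow; used to rank very strong signals
  log_p <- log(2) + stats::pt(-abs(t_stat), df, log.p = TRUE)
  list(t_stat = t_stat, p_value = exp(log_p), log_p = log_p, df = df)
}

zone_stat_row <- function(zone, q, pos_mask) {
  x <- q[pos_mask]; y <- q[!pos_mask]
  wt <- welch_t_test(x, y)
  data.frame(zone_lo = zone[1], zone_hi = zone[2],
             mean_pos = mean(x), mean_neg = mean(y),
             sd_pos = stats::sd(x), sd_neg = stats::sd(y),
             t_stat = wt$t_stat, p_value = wt$p_value, log_p = wt$log_p,
             n_pos = length(x), n_neg = length(y))
}

#' Scan anchor-pair zones for group discrimination
#'
#' Enumerates every pair of anchor wavenumbers as a candidate zone
#' (padded outward by `pad` so a band centred on an anchor is
#' integrated in full), keeps zones at least `min_width` wide, scores
#' each zone by the Welch p value of its per-sample quantifications
#' between the two label groups, ranks ascending by p (ties: wider zone
#' first, then lower `lo`), and greedily drops any zone overlapping an
#' already-retained better-ranked zone until `max_zones` remain.
#' Deterministic.
#'
#' @param X samples-by-wavenumber matrix of normalized spectra.
#' @param labels per-sample binary labels.
#' @param anchors candidate boundary wavenumbers (e.g. from
#'   [loading_extrema()]).
#' @param wavenumber shared grid of `X`.
#' @param positive label of the positive group (default: first level).
#' @param min_width minimum zone width in cm^-1 (default 30).
#' @param max_zones zones to retain (default 2).
#' @param pad outward extension of each candidate zone boundary in
#'   cm^-1 (default 6, half the default band linewidth), clipped to the
#'   grid.
#' @return data.frame of zone statistics, best first; zero rows (with a
#'   warning) when no anchor pair meets `min_width`.
#' @export
scan_zones <- function(X, labels, anchors, wavenumber,
                       positive = NULL, min_width = 30, max_zones = 2,
                       pad = 6) {
  stopifnot(min_width > 0, pad >= 0)
  if (length(anchors) < 2) stop("need at least 2 anchors")
  labels <- as.character(labels)
  if (is.null(positive)) positive <- sort(unique(labels))[1]
  pos_mask <- labels == positive
  anchors <- sort(anchors)
  wlo <- wavenumber[1]; whi <- wavenumber[length(wavenumber)]
  cand <- list()
  for (i in seq_along(anchors)) for (j in seq_along(anchors)) {
    if (j <= i) next
    z <- c(max(wlo, anchors[i] - pad), min(whi, anchors[j] + pad))
    if (z[2] - z[1] >= min_width)
      cand[[length(cand) + 1L]] <- z
  }
  cand <- unique(cand)
  if (!length(cand)) {
    warning("no anchor pair meets min_width; empty scan result")
    return(data.frame(zone_lo = numeric(0), zone_hi = numeric(0),
                      mean_pos = numeric(0), mean_neg = numeric(0),
                      sd_pos = numeric(0), sd_neg = numeric(0),
                      t_stat = numeric(0), p_value = numeric(0),
                      log_p = numeric(0), n_pos = integer(0),
                      n_neg = integer(0)))
  }
  stats_df <- do.call(rbind, lapply(cand, function(z)
    zone_stat_row(z, quantify_zone_matrix(X, wavenumber, z), pos_mask)))
  width <- stats_df$zone_hi - stats_df$zone_lo
  ord <- order(stats_df$log_p, -width, stats_df$zone_lo)
  stats_df <- stats_df[ord, ]
  kept <- integer(0)
  for (r in seq_len(nrow(stats_df))) {
    overlaps <- any(vapply(kept, function(k)
      stats_df$zone_lo[r] <= stats_df$zone_hi[k] &&
        stats_df$zone_hi[r] >= stats_df$zone_lo[k], logical(1)))
    if (!overlaps) kept <- c(kept, r)
    if (length(kept) >= max_zones) break
  }
  out <- stats_df[kept, ]
  rownames(out) <- NULL
  out
}

#' Zone statistics and boxplot-ready quantifications
#'
#' For each zone: group means, SDs, Welch t and p on the per-sample
#' quantifications, plus the raw values (with quartiles) for box
#' rendering. Samples with a missing label are excluded with a warning.
#'
#' @inheritParams scan_zones
#' @param zones list of numeric `c(lo, hi)` zones.
#' @return list with `stats` (data.frame, one row per zone) and
#'   `quantifications` (long data.frame: zone, sample_id, label, value).
#' @export
group_difference_report <- function(X, labels, zones, wavenumber,
                                    positive = NULL) {
  if (!length(zones)) stop("zones must be non-empty")
  labels <- as.character(labels)
  keep <- !is.na(labels)
  if (any(!keep)) {
    warning(sum(!keep), " sample(s) excluded for missing labels")
    X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  }
  if (is.null(positive)) positive <- sort(unique(labels))[1]
  pos_mask <- labels == positive
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  stats_rows <- list(); quant_rows <- list()
  for (z in zones) {
    q <- quantify_zone_matrix(X, wavenumber, z)
    stats_rows[[length(stats_rows) + 1L]] <- zone_stat_row(z, q, pos_mask)
    quant_rows[[length(quant_rows) + 1L]] <- data.frame(
      zone = sprintf("%g-%g", z[1], z[2]), sample_id = ids,
      label = labels, value = q, stringsAsFactors = FALSE)
  }
  quants <- do.call(rbind, quant_rows)
  box <- do.call(rbind, lapply(split(quants, list(quants$zone, quants$label)),
    function(d) data.frame(zone = d$zone[1], label = d$label[1],
                           q1 = stats::quantile(d$value, 0.25, names = FALSE),
                           median = stats::median(d$value),
                           q3 = stats::quantile(d$value, 0.75, names = FALSE))))
  rownames(box) <- NULL
  list(stats = do.call(rbind, stats_rows), quantifications = quants,
       boxes = box)
}

#' Jaccard overlap of two closed intervals
#'
#' @param a,b numeric `c(lo, hi)` intervals.
#' @return intersection length / union length (0 when disjoint).
#' @export
zone_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  inter / union
}
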