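#' Pseudo-Voigt line shape
#'
#' Weighted blend of a Lorentzian and a Gaussian of common centre and
#' full width at half maximum, the standard solution-phase Raman band
#' model. Peak height equals `amplitude`.
#'
#' @param w wavenumbers at which to evaluate (cm^-1).
#' @param center band centre (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param amplitude peak height (intensity units), >= 0.
#' @param shape_mix Lorentzian fraction in `[0, 1]` (0 = pure Gaussian).
#' @return numeric vector of intensities.
#' @export
pseudo_voigt <- function(w, center, fwhm, amplitude, shape_mix = 0.7) {
  stopifnot(fwhm > 0, amplitude >= 0, shape_mix >= 0, shape_mix <= 1)
  x <- (w - center) / fwhm
  lor <- 1 / (1 + 4 * x^2)
  gau <- exp(-4 * log(2) * x^2)
  amplitude * (shape_mix * lor + (1 - shape_mix) * gau)
}

#' Default band table for synthetic follicular-fluid spectra
#'
#' Narrow bands at the assigned fingerprint positions (tryptophan 758,
#' proline/tyrosine 852, protein backbone 936, phenylalanine 1003,
#' C-C/C-N protein 1156, beta-carotene 1516/1518, 1590, 1627, amide
#' carbonyl 1668 cm^-1) plus broad filler envelopes that mimic the
#' overlapping protein/lipid background of a biofluid spectrum.
#' Amplitudes are fixed package defaults on an arbitrary count scale.
#'
#' @return data.frame with columns `center`, `fwhm`, `amplitude`,
#'   `shape_mix`.
#' @export
default_peaks <- function() {
  narrow <- data.frame(
    center    = c(758, 852, 936, 1003, 1156, 1516, 1518, 1590, 1627, 1668),
    fwhm      = 12,
    amplitude = c(0.20, 0.20, 0.15, 1.576, 1.261, 0.45, 0.45, 0.45, 0.45, 0.45),
    shape_mix = 0.7)
  filler <- data.frame(
    center    = c(700, 870, 1250, 1310, 1445, 1520, 1600, 1655),
    fwhm      = c(80, 70, 90, 70, 60, 100, 90, 70),
    amplitude = c(0.15, 0.20, 0.30, 0.25, 0.123, 0.123, 0.123, 0.123),
    shape_mix = 0.3)
  rbind(narrow, filler)
}

#' Baseline specification for the synthetic generator
#'
#' A smooth non-negative floor standing in for residual fluorescence
#' after background subtraction: an exponential decay plus a low-order
#' polynomial in the normalized wavenumber coordinate.
#'
#' @param poly_coeffs polynomial coefficients (constant first) over
#'   `u = (w - min) / (max - min)`.
#' @param fluor_amplitude amplitude of the exponential component.
#' @param fluor_decay decay constant (cm^-1).
#' @return list of class `baseline_spec`.
#' @export
baseline_spec <- function(poly_coeffs = 0.0425,
                          fluor_amplitude = 0.085, fluor_decay = 600) {
  structure(list(poly_coeffs = poly_coeffs,
                 fluor_amplitude = fluor_amplitude,
                 fluor_decay = fluor_decay),
            class = "baseline_spec")
}

eval_baseline <- function(bl, w) {
  u <- (w - min(w)) / (max(w) - min(w))
  poly <- rowSums(outer(u, seq_along(bl$poly_coeffs) - 1, `^`) *
                    rep(bl$poly_coeffs, each = length(u)))
  y <- bl$fluor_amplitude * exp(-(w - min(w)) / bl$fluor_decay) + poly
  if (any(y < 0)) stop("baseline is negative on the grid")
  y
}

#' Class-specific zone gain
#'
#' Multiplicative gain applied to the amplitude of every band whose
#' centre lies inside `zone`, for spectra of class `class`. This is the
#' mechanism by which group differences are injected: because spectra
#' are later vector-normalized, raising one zone necessarily depresses
#' the rest of the fingerprint, reproducing opposite-signed zone
#' findings from a single-zone perturbation.
#'
#' @param class class label the gain applies to (e.g. `"PCOS"`).
#' @param zone numeric `c(lo, hi)` in cm^-1.
#' @param gain multiplicative factor, > 0.
#' @return list of class `group_effect`.
#' @export
group_effect <- function(class, zone, gain) {
  stopifnot(gain > 0, length(zone) == 2, zone[1] < zone[2])
  structure(list(class = as.character(class),
                 zone = as.numeric(zone), gain = gain),
            class = "group_effect")
}

#' Configuration of the synthetic-cohort generator
#'
#' @param grid wavenumber grid (default the 50--2000 cm^-1 acquisition
#'   range at 1 cm^-1).
#' @param peaks band table as from [default_peaks()].
#' @param baseline a [baseline_spec()].
#' @param effects list of [group_effect()]s.
#' @param n_per_group samples per group (default 150, the cohort arm
#'   size emulated here; the pregnancy task redistributes `2*n_per_group`
#'   samples at the 85:65 success:failure ratio).
#' @param replicates replicate spectra per sample (default 5).
#' @param replicate_jitter_sd SD of the per-replicate multiplicative
#'   intensity jitter (default 0.02).
#' @param baseline_jitter_sd SD of the per-sample log-normal factor on
#'   the baseline amplitude (default 0.1): residual fluorescence level
#'   varies between patients. Under vector normalization this shifts the
#'   baseline-to-band share of every zone coherently, giving zone
#'   quantifications a noise floor that does not shrink with zone width.
#' @param sample_amp_sd SD of the per-sample log-normal band-amplitude
#'   variation (default 0.05): each biological sample draws an
#'   independent multiplicative factor `exp(N(0, sample_amp_sd))` per
#'   band, emulating compositional variation between patients. Unlike
#'   the whole-spectrum replicate jitter this survives vector
#'   normalization, and at the default it yields per-sample zone
#'   quantifications spread on the order of the printed +/- 0.001.
#' @param noise_sd SD of additive Gaussian noise; default 0.5% of the
#'   tallest band amplitude.
#' @param seed integer RNG seed used by [generate_dataset()].
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid = wavenumber_grid(50, 2000, 1),
                             peaks = default_peaks(),
                             baseline = baseline_spec(),
                             effects = list(),
                             n_per_group = 150,
                             replicates = 5,
                             replicate_jitter_sd = 0.02,
                             sample_amp_sd = 0.05,
                             baseline_jitter_sd = 0.1,
                             noise_sd = NULL,
                             seed = 1L) {
  if (is.null(noise_sd)) noise_sd <- 0.005 * max(peaks$amplitude)
  stopifnot(n_per_group >= 2, replicates >= 1,
            noise_sd >= 0, replicate_jitter_sd >= 0, sample_amp_sd >= 0,
            baseline_jitter_sd >= 0)
  structure(list(grid = grid, peaks = peaks, baseline = baseline,
                 effects = effects, n_per_group = n_per_group,
                 replicates = replicates,
                 replicate_jitter_sd = replicate_jitter_sd,
                 sample_amp_sd = sample_amp_sd,
                 baseline_jitter_sd = baseline_jitter_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# product of gains applying to each peak for a given class
peak_gains <- function(config, class) {
  g <- rep(1, nrow(config$peaks))
  for (ef in config$effects) {
    if (ef$class != class) next
    hit <- config$peaks$center >= ef$zone[1] & config$peaks$center <= ef$zone[2]
    g[hit] <- g[hit] * ef$gain
  }
  g
}

#' Noiseless class-mean spectrum of a synthetic configuration
#'
#' Baseline plus the gain-adjusted band sum for one class; this is the
#' expected replicate spectrum before jitter and noise, and the quantity
#' the calibration routine solves on.
#'
#' @param config a [synthetic_config()].
#' @param class class label (effects matching this label are applied).
#' @return a `raman_spectrum` on the acquisition grid.
#' @export
class_mean_spectrum <- function(config, class) {
  w <- config$grid
  y <- eval_baseline(config$baseline, w)
  g <- peak_gains(config, class)
  for (i in seq_len(nrow(config$peaks))) {
    p <- config$peaks[i, ]
    y <- y + pseudo_voigt(w, p$center, p$fwhm, g[i] * p$amplitude, p$shape_mix)
  }
  raman_spectrum(w, y)
}

task_classes <- function(task = c("pcos", "blastocyst", "pregnancy")) {
  switch(match.arg(task),
         pcos = c("PCOS", "nonPCOS"),
         blastocyst = c("HQ", "LQ"),
         pregnancy = c("success", "failure"))
}

# class carrying the injected "raised 993-1165 / lowered 1439-1678"
# metabolic pattern for each task
task_effect_class <- function(task = c("pcos", "blastocyst", "pregnancy")) {
  switch(match.arg(task), pcos = "PCOS", blastocyst = "LQ",
         pregnancy = "failure")
}

#' Generate a labeled synthetic cohort
#'
#' Each biological sample draws per-band amplitude factors
#' `exp(N(0, sample_amp_sd))` around the class-mean band amplitudes and
#' a baseline-level factor `exp(N(0, baseline_jitter_sd))`;
#' each of its replicate spectra is that sample spectrum scaled by a
#' multiplicative jitter `1 + N(0, replicate_jitter_sd)`, plus additive
#' `N(0, noise_sd)` noise, clipped at zero. Labels follow the task:
#' equal groups of `n_per_group` for the PCOS and blastocyst tasks; the
#' pregnancy task splits `2*n_per_group` samples 85:65. Deterministic
#' given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param task `"pcos"`, `"blastocyst"` or `"pregnancy"`.
#' @return a `spectrum_set` with the task label column filled in.
#' @export
generate_dataset <- function(config, task = c("pcos", "blastocyst", "pregnancy")) {
  task <- match.arg(task)
  classes <- task_classes(task)
  total <- 2L * config$n_per_group
  counts <- if (task == "pregnancy") {
    n_pos <- round(total * 85 / 150)
    c(n_pos, total - n_pos)
  } else c(config$n_per_group, config$n_per_group)
  set.seed(config$seed)
  w <- config$grid
  n_w <- length(w)
  base <- eval_baseline(config$baseline, w)
  n_pk <- nrow(config$peaks)
  # per-band profiles (unit amplitude) so sample spectra are cheap sums
  profiles <- vapply(seq_len(n_pk), function(i) {
    p <- config$peaks[i, ]
    pseudo_voigt(w, p$center, p$fwhm, 1, p$shape_mix)
  }, numeric(n_w))
  ids <- character(0); labs <- character(0); spectra <- list()
  for (k in seq_along(classes)) {
    cl <- classes[k]
    amps <- peak_gains(config, cl) * config$peaks$amplitude
    for (i in seq_len(counts[k])) {
      id <- sprintf("%s_%03d", cl, i)
      samp_amps <- amps * exp(stats::rnorm(n_pk, 0, config$sample_amp_sd))
      bl_fac <- exp(stats::rnorm(1, 0, config$baseline_jitter_sd))
      samp <- bl_fac * base + as.numeric(profiles %*% samp_amps)
      m <- matrix(0, nrow = config$replicates, ncol = n_w)
      for (r in seq_len(config$replicates)) {
        jit <- 1 + stats::rnorm(1, 0, config$replicate_jitter_sd)
        m[r, ] <- pmax(0, samp * jit + stats::rnorm(n_w, 0, config$noise_sd))
      }
      spectra[[id]] <- m
      ids <- c(ids, id); labs <- c(labs, cl)
    }
  }
  meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  col <- switch(task, pcos = "group_pcos", blastocyst = "blastocyst",
                pregnancy = "pregnancy")
  meta[[col]] <- labs
  spectrum_set(meta, w, spectra)
}

# expected post-normalization zone quantification of a class mean,
# after fingerprint cropping -- the calibration objective
noiseless_zone_quant <- function(config, class, zone,
                                 fingerprint = c(600, 1800)) {
  sp <- crop_fingerprint(class_mean_spectrum(config, class), fingerprint)
  quantify_zone(vector_normalize(sp), zone)
}

#' Calibrate class gains to printed zone-quantification targets
#'
#' Adjusts the two per-class zone gains (on `zoneA` and `zoneB`) so that
#' the noiseless class-mean spectra, after fingerprint cropping and
#' vector normalization, reproduce four target width-averaged zone
#' quantifications. Each gain is found by 1-D monotone root finding
#' (zone quantification is strictly increasing in its own zone gain),
#' alternating between the two zones of a class until the residual falls
#' below `tol`; the two classes are independent after normalization.
#'
#' @param config a [synthetic_config()]; existing effects for the two
#'   classes on these zones are replaced.
#' @param zoneA,zoneB numeric `c(lo, hi)` zones (cm^-1).
#' @param targets numeric of length 4: `(meanA_pos, meanA_neg,
#'   meanB_pos, meanB_neg)`, each in (0, 1).
#' @param classes character of length 2, the (positive, negative) class
#'   labels (default `c("PCOS", "nonPCOS")`).
#' @param fingerprint analysis region for normalization.
#' @param tol convergence tolerance on the quantifications (default 1e-5).
#' @param norm_balance when `TRUE` (default), a third knob — a gain on
#'   the narrow `balance_zone` bands of the first class — is root-found
#'   so the two calibrated class spectra have equal Euclidean norm over
#'   the fingerprint. Equal norms localize the between-class difference
#'   to the calibrated zones: without this, the class whose zones carry
#'   less total intensity is scaled up everywhere by normalization,
#'   smearing a spurious flat difference across the whole fingerprint.
#' @param balance_zone narrow sub-zone (default the carotenoid doublet
#'   `c(1510, 1525)`) whose peak-vs-broad share is adjusted; must lie
#'   inside `zoneA` or `zoneB` so the zone targets stay in force.
#' @return the calibrated `synthetic_config`.
#' @export
calibrate_group_gains <- function(config, zoneA, zoneB, targets,
                                  classes = c("PCOS", "nonPCOS"),
                                  fingerprint = c(600, 1800), tol = 1e-5,
                                  norm_balance = TRUE,
                                  balance_zone = c(1510, 1525)) {
  stopifnot(length(targets) == 4, all(targets > 0 & targets < 1),
            length(classes) == 2)
  tmat <- matrix(targets, nrow = 2, byrow = FALSE,
                 dimnames = list(classes, c("A", "B")))
  # drop any existing effects on these zones (or the balance zone) for
  # the two classes, so calibration is idempotent
  keep <- vapply(config$effects, function(ef) {
    !(ef$class %in% classes &&
        (isTRUE(all.equal(ef$zone, as.numeric(zoneA))) ||
         isTRUE(all.equal(ef$zone, as.numeric(zoneB))) ||
         isTRUE(all.equal(ef$zone, as.numeric(balance_zone)))))
  }, logical(1))
  base_effects <- config$effects[keep]

  solve_gains <- function(extra) {
    cfg0 <- config
    cfg0$effects <- c(base_effects, extra)
    for (cl in classes) {
      gA <- 1; gB <- 1
      quant <- function(gA, gB, zone) {
        cfg <- cfg0
        cfg$effects <- c(cfg$effects,
                         list(group_effect(cl, zoneA, gA),
                              group_effect(cl, zoneB, gB)))
        noiseless_zone_quant(cfg, cl, zone, fingerprint)
      }
      converged <- FALSE
      for (it in 1:60) {
        gA <- stats::uniroot(function(g) quant(g, gB, zoneA) - tmat[cl, "A"],
                             interval = c(1e-3, 1e3), tol = 1e-9,
                             extendInt = "upX")$root
        gB <- stats::uniroot(function(g) quant(gA, g, zoneB) - tmat[cl, "B"],
                             interval = c(1e-3, 1e3), tol = 1e-9,
                             extendInt = "upX")$root
        res <- max(abs(quant(gA, gB, zoneA) - tmat[cl, "A"]),
                   abs(quant(gA, gB, zoneB) - tmat[cl, "B"]))
        if (res < tol) { converged <- TRUE; break }
      }
      if (!converged)
        stop(sprintf("calibration did not converge for class %s (residual %.3g)",
                     cl, res))
      cfg0$effects <- c(cfg0$effects,
                        list(group_effect(cl, zoneA, gA),
                             group_effect(cl, zoneB, gB)))
    }
    cfg0
  }

  if (!norm_balance) return(solve_gains(list()))

  fp_norm <- function(cfg, cl)
    sqrt(sum(crop_fingerprint(class_mean_spectrum(cfg, cl),
                              fingerprint)$intensity^2))
  balance_effect <- function(g) {
    if (abs(g - 1) < 1e-10) list()
    else list(group_effect(classes[1], balance_zone, g))
  }
  gap <- function(g) {
    cal <- solve_gains(balance_effect(g))
    fp_norm(cal, classes[1]) / fp_norm(cal, classes[2]) - 1
  }
  safe_gap <- function(g) tryCatch(gap(g), error = function(e) NA_real_)
  # a residual relative norm mismatch of this size leaks a between-class
  # difference density orders of magnitude below the injected zone
  # effects; no balancing is needed
  if (abs(gap(1)) < 2e-4) return(solve_gains(list()))
  # bracket the norm-equalizing sub-zone gain, then root-find
  gs <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 9, 14)
  vals <- vapply(gs, safe_gap, numeric(1))
  gs <- gs[!is.na(vals)]; vals <- vals[!is.na(vals)]
  if (length(gs) < 2)
    stop("norm balancing failed: calibration infeasible across sub-zone gains")
  sc <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (!length(sc))
    stop("norm balancing failed: no sub-zone gain equalizes class norms ",
         sprintf("(best residual %.3g)", min(abs(vals))))
  # prefer the bracket closest to a neutral gain of 1
  i <- sc[which.min(abs((gs[sc] + gs[sc + 1]) / 2 - 1))]
  root <- stats::uniroot(gap, c(gs[i], gs[i + 1]), tol = 1e-7)$root
  solve_gains(balance_effect(root))
}
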