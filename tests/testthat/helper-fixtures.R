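# shared fixtures: all built in code at test time

ZONE_A <- c(993, 1165)
ZONE_B <- c(1439, 1678)
PRINTED_TARGETS <- c(0.0286, 0.0274, 0.0319, 0.0337)

# tiny noiseless config: every sample of a class is the class mean
noiseless_config <- function(n = 3, replicates = 1, effects = list(), seed = 1) {
  synthetic_config(n_per_group = n, replicates = replicates,
                   replicate_jitter_sd = 0, sample_amp_sd = 0,
                   baseline_jitter_sd = 0, noise_sd = 0,
                   effects = effects, seed = seed)
}

# two classes with disjoint discriminative bands, zero noise
separable_config <- function(n = 10, seed = 1) {
  noiseless_config(n = n, effects = list(
    group_effect("HQ", c(990, 1016), 2),
    group_effect("LQ", c(1330, 1350), 4)), seed = seed)
}

# cached calibrated configuration (calibration is deterministic)
calibrated_config <- local({
  cache <- NULL
  function(n_per_group = 40) {
    if (is.null(cache))
      cache <<- calibrate_group_gains(
        synthetic_config(n_per_group = n_per_group, seed = 1),
        ZONE_A, ZONE_B, PRINTED_TARGETS)
    cfg <- cache
    cfg$n_per_group <- n_per_group
    cfg
  }
})

write_tmp_spectrum <- function(w, y, header = TRUE) {
  f <- tempfile(fileext = ".csv")
  lines <- paste(w, y, sep = ",")
  if (header) lines <- c("wavenumber_cm-1,intensity", lines)
  writeLines(lines, f)
  f
}
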