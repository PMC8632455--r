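# ramanff

Chemometric analysis of follicular-fluid (FF) Raman spectra: find the
wavenumber zones that separate two patient groups, quantify them, and
classify clinical outcomes from the spectra.

FF surrounds the oocyte, and its Raman fingerprint (600–1800 cm⁻¹)
indexes its metabolic composition band by band. Given per-sample
replicate spectra and binary labels — PCOS vs. non-PCOS, high- vs.
low-quality blastocyst, pregnancy success vs. failure — the package
runs two arms over a shared preprocessing core (background
subtraction, fingerprint cropping, vector normalization, replicate
averaging):

* **Discovery.** Mean-centred group contrasts and PCA; the salient
  extrema of the first loading anchor candidate zones; every anchor
  pair is scored by the Welch t test on per-sample width-averaged band
  integrals `q(z) = ∫_z ŝ(w) dw / |z|` (with `ŝ` the unit-norm
  spectrum), and the best non-overlapping zones are reported with
  group means, SDs, t and p.
* **Classification.** A fully connected network (1201 inputs → 64 relu
  → 64 relu → softmax, cross-entropy, adam, dropout, 1% error-threshold
  stopping) over wavelet-denoised spectra, evaluated by stratified 4:1
  holdout, five-fold cross-validation (ROC/AUC mean ± SD), or
  leave-one-out; confusion matrices with per-class precision,
  sensitivity, F1 and overall accuracy.

Because no public FF Raman cohort exists, the package ships a tested
synthetic-cohort generator — pseudo-Voigt bands at the assigned FF
positions on a fluorescence baseline, with replicate-, sample- and
point-level noise — whose class effects are *calibrated* so the
noiseless group means reproduce published zone quantifications
(e.g. 0.0286 vs. 0.0274 over 993–1165 cm⁻¹). See the methods vignette
(`vignettes/raman-follicular-fluid.Rmd`) for the model and design
decisions.

## Worked example

```r
library(ramanff)

cal <- calibrate_group_gains(synthetic_config(n_per_group = 40, seed = 1),
                             c(993, 1165), c(1439, 1678),
                             c(0.0286, 0.0274, 0.0319, 0.0337))
cohort <- generate_dataset(cal, "pcos")
pp     <- preprocess_set(cohort)
labels <- task_labels(cohort, "pcos")
pca    <- pca_decompose(pp$X, 2, pp$wavenumber)
scan_zones(pp$X, labels, loading_extrema(pca, 1), pp$wavenumber,
           positive = "PCOS")
#>   zone_lo zone_hi   mean_pos   mean_neg       sd_pos       sd_neg    t_stat
#> 1    1493    1685 0.03490247 0.03707898 0.0005990541 0.0006963364 -14.98597
#> 2     997    1162 0.02758906 0.02625676 0.0004290459 0.0004428580  13.66538
#>        p_value     log_p n_pos n_neg
#> 1 1.944564e-24 -54.59700    40    40
#> 2 2.180449e-22 -49.87734    40    40
```

The two retained zones recover the injected effects: the 997–1162 cm⁻¹
zone (phenylalanine/protein region) is *higher* in the positive group
and the 1493–1685 cm⁻¹ zone (carotenoid/carbonyl region) *lower*, each
with an extreme Welch p — the opposite-signed two-zone pattern the
generator was calibrated to. Group means (~0.026–0.037) are unitless
width-averaged intensities of unit-norm spectra; a flat spectrum would
sit at 1/√1201 ≈ 0.0289 in every zone.

End-to-end runs with JSON/CSV reports:

```r
cfg <- pipeline_config(task = "pcos", synthetic = cal, seed = 1)
run_discovery(cfg, out_dir = "out")       # report.json, quantifications.csv
run_classification(cfg, out_dir = "out")  # metrics.json
```

or from a shell, `Rscript inst/cli/ramanff.R run-all --task pcos --n 40
--seed 1 --out out` (subcommands: `generate`, `discover`, `classify`,
`run-all`).

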