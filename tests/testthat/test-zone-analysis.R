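test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(5)
  X <- matrix(rnorm(12), 4, 3)
  colnames(X) <- c("600", "601", "602")
  pca <- pca_decompose(X, 2)
  # oracle: eigenvectors of the sample covariance of centered columns
  C <- stats::cov(X)
  eig <- eigen(C, symmetric = TRUE)
  for (k in 1:2) {
    v <- eig$vectors[, k]
    if (v[which.max(abs(v))] < 0) v <- -v          # same sign convention
    expect_equal(as.numeric(pca$loadings[k, ]), v, tolerance = 1e-8)
  }
  expect_equal(pca$explained_variance_fraction,
               (eig$values / sum(eig$values))[1:2], tolerance = 1e-8)
  # scores are centered projections
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(as.numeric(pca$scores[, 1]),
               as.numeric(Xc %*% pca$loadings[1, ]), tolerance = 1e-8)
  expect_lt(max(abs(colMeans(pca$scores))), 1e-10)
})

test_that("rank-1 data put all variance on the first component", {
  set.seed(6)
  pattern <- rnorm(30)
  X <- outer(rnorm(8), pattern)
  colnames(X) <- as.character(seq_len(30))
  pca <- pca_decompose(X, 2)
  expect_equal(pca$explained_variance_fraction[1], 1, tolerance = 1e-8)
  expect_error(pca_decompose(X, 10), "n_components")
})

test_that("PCA reconstruction from all components is exact", {
  set.seed(8)
  X <- matrix(rnorm(6 * 20), 6, 20)
  colnames(X) <- as.character(seq_len(20))
  pca <- pca_decompose(X, 5)
  Xc <- sweep(X, 2, pca$center)
  recon <- pca$scores %*% pca$loadings
  expect_equal(recon, Xc, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("loading extrema find injected band positions and skip flat loadings", {
  w <- 600:1800
  single <- exp(-0.5 * ((w - 1003) / 6)^2)
  pca <- list(loadings = matrix(single, 1), wavenumber = w)
  class(pca) <- "raman_pca"
  expect_equal(loading_extrema(pca, 1), 1003)
  flat <- list(loadings = matrix(rep(0.5, 1201), 1), wavenumber = w)
  class(flat) <- "raman_pca"
  expect_length(loading_extrema(flat, 1), 0)
  expect_error(loading_extrema(pca, 3), "not present")
})

test_that("loading extrema on a synthetic two-effect cohort hit both bands", {
  cfg <- synthetic_config(n_per_group = 20, replicates = 2, seed = 17,
                          effects = list(group_effect("PCOS", c(1000, 1006), 1.3),
                                         group_effect("nonPCOS", c(1513, 1521), 1.3)))
  set <- generate_dataset(cfg, "pcos")
  pp <- preprocess_set(set)
  pca <- pca_decompose(pp$X, 2, pp$wavenumber)
  anchors <- loading_extrema(pca, 1)
  expect_true(any(abs(anchors - 1003) <= 5))
  expect_true(any(abs(anchors - 1517) <= 5))
})

test_that("zone quantification has the trapezoid closed forms", {
  w <- 600:1800
  v <- 0.02
  flat <- raman_spectrum(w, rep(v, 1201))
  expect_equal(quantify_zone(flat, c(993, 1165)), v, tolerance = 1e-12)
  # linear ramp a -> b over the zone averages to (a+b)/2
  a <- 0.01; b <- 0.05
  y <- rep(0.01, 1201)
  inz <- w >= 1000 & w <= 1200
  y[inz] <- seq(a, b, length.out = sum(inz))
  ramp <- raman_spectrum(w, y)
  expect_equal(quantify_zone(ramp, c(1000, 1200)), (a + b) / 2,
               tolerance = 1e-12)
  expect_error(quantify_zone(flat, c(500, 700)), "outside")
})

test_that("zone quantification ignores grid points outside the zone", {
  set.seed(9)
  w <- 600:1800
  y <- abs(rnorm(1201))
  y2 <- y
  outside <- w < 993 | w > 1165
  y2[outside] <- y2[outside] * 10
  q1 <- quantify_zone(raman_spectrum(w, y), c(993, 1165))
  q2 <- quantify_zone(raman_spectrum(w, y2), c(993, 1165))
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("welch test agrees with the reference implementation", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  got <- welch_t_test(x, y)
  ref <- t.test(x, y, var.equal = FALSE)
  expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-8)
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    got <- welch_t_test(x, y)
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
    swapped <- welch_t_test(y, x)
    expect_equal(swapped$t_stat, -got$t_stat, tolerance = 1e-12)
    expect_equal(swapped$p_value, got$p_value, tolerance = 1e-12)
  }
})

test_that("welch test handles degenerate inputs per contract", {
  same <- welch_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  diff <- welch_t_test(c(2, 2), c(3, 3))
  expect_equal(diff$p_value, 0)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("zone scanning is deterministic and respects min_width", {
  cal <- calibrated_config(20)
  cal$seed <- 77L
  set <- generate_dataset(cal, "pcos")
  pp <- preprocess_set(set)
  lab <- task_labels(set, "pcos")
  pca <- pca_decompose(pp$X, 2, pp$wavenumber)
  anchors <- loading_extrema(pca, 1)
  s1 <- scan_zones(pp$X, lab, anchors, pp$wavenumber, "PCOS")
  s2 <- scan_zones(pp$X, lab, anchors, pp$wavenumber, "PCOS")
  expect_identical(s1, s2)
  expect_true(all(s1$zone_hi - s1$zone_lo >= 30))
  expect_warning(
    empty <- scan_zones(pp$X, lab, c(1000, 1010), pp$wavenumber, "PCOS",
                        min_width = 200, pad = 0),
    "min_width")
  expect_equal(nrow(empty), 0)
  expect_error(scan_zones(pp$X, lab, 1003, pp$wavenumber), "2 anchors")
})

test_that("permuted labels rarely reach extreme significance", {
  cal <- calibrated_config(20)
  cal$seed <- 78L
  set <- generate_dataset(cal, "pcos")
  pp <- preprocess_set(set)
  lab <- task_labels(set, "pcos")
  pca <- pca_decompose(pp$X, 2, pp$wavenumber)
  anchors <- loading_extrema(pca, 1)
  set.seed(42)
  hits <- 0L
  n_perm <- 40L
  for (i in seq_len(n_perm)) {
    perm <- sample(lab)
    sc <- scan_zones(pp$X, perm, anchors, pp$wavenumber, "PCOS")
    if (nrow(sc) && min(sc$p_value) < 0.001) hits <- hits + 1L
  }
  # selection bias inflates the best-of-candidates p, but extreme
  # significance should stay rare under the null
  expect_lte(hits / n_perm, 0.15)
})

test_that("group difference report matches a hand-computed micro-case", {
  w <- 600:1800
  mk <- function(level) {
    y <- rep(0.02, 1201)
    y[w >= 1000 & w <= 1100] <- level
    y
  }
  X <- rbind(mk(0.030), mk(0.032), mk(0.020), mk(0.022))
  rownames(X) <- paste0("s", 1:4)
  lab <- c("pos", "pos", "neg", "neg")
  rep_ <- group_difference_report(X, lab, list(c(1000, 1100)), w,
                                  positive = "pos")
  st <- rep_$stats
  expect_equal(st$mean_pos, 0.031)
  expect_equal(st$mean_neg, 0.021)
  expect_equal(st$sd_pos, sd(c(0.030, 0.032)))
  # hand Welch: t = (0.031-0.021)/sqrt(1e-6/2/... ) computed directly
  sp2 <- var(c(0.030, 0.032)) / 2 + var(c(0.020, 0.022)) / 2
  expect_equal(st$t_stat, 0.01 / sqrt(sp2), tolerance = 1e-10)
  expect_equal(nrow(rep_$quantifications), 4)
  X5 <- rbind(X, mk(0.04))
  rownames(X5) <- paste0("s", 1:5)
  expect_warning(
    rep5 <- group_difference_report(X5, c("pos", "pos", "neg", "neg", NA),
                                    list(c(1000, 1100)), w, positive = "pos"),
    "excluded")
  expect_equal(rep5$stats$mean_pos, st$mean_pos)
})

test_that("null cohorts show no systematic group difference", {
  cfg <- synthetic_config(n_per_group = 25, replicates = 2, seed = 13)
  set <- generate_dataset(cfg, "pcos")
  pp <- preprocess_set(set)
  lab <- task_labels(set, "pcos")
  rep_ <- group_difference_report(pp$X, lab, list(ZONE_A, ZONE_B),
                                  pp$wavenumber, positive = "PCOS")
  # under the null the Welch p should be unremarkable in both zones
  expect_true(all(rep_$stats$p_value > 1e-4))
})

test_that("interval Jaccard overlap behaves at the boundaries", {
  expect_equal(zone_jaccard(c(0, 10), c(0, 10)), 1)
  expect_equal(zone_jaccard(c(0, 10), c(20, 30)), 0)
  expect_equal(zone_jaccard(c(0, 10), c(5, 15)), 1 / 3)
})
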