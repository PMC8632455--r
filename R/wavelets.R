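# Periodized orthogonal discrete wavelet transform (haar and db4) used by
# the spectral denoiser. Signals are symmetrically padded on the right to a
# multiple of 2^level before the transform and truncated after inverse
# transform, so arbitrary lengths (e.g. the 1201-point fingerprint) are
# supported.

wavelet_filters <- function(family = c("db4", "haar")) {
  family <- match.arg(family)
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    # Daubechies-4 (8-tap, 4 vanishing moments) scaling filter
    db4 = c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror high-pass
  list(h = h, g = g)
}

# one analysis step of the periodized DWT; length(v) must be even
dwt_step <- function(v, flt) {
  N <- length(v); L <- length(flt$h)
  idx <- (outer(2 * (seq_len(N / 2) - 1), 0:(L - 1), `+`) %% N) + 1
  V <- matrix(v[idx], ncol = L)
  list(approx = as.numeric(V %*% flt$h), detail = as.numeric(V %*% flt$g))
}

# inverse of dwt_step (transpose of the orthogonal analysis operator)
idwt_step <- function(approx, detail, flt) {
  N <- 2L * length(approx); L <- length(flt$h)
  v <- numeric(N)
  base <- 2 * (seq_along(approx) - 1)
  for (n in 0:(L - 1)) {
    pos <- ((base + n) %% N) + 1
    v[pos] <- v[pos] + approx * flt$h[n + 1] + detail * flt$g[n + 1]
  }
  v
}

# multilevel decomposition: list(approx, details = list(level1..levelJ))
# details[[1]] is the finest level
dwt_multilevel <- function(v, flt, level) {
  details <- vector("list", level)
  a <- v
  for (j in seq_len(level)) {
    if (length(a) %% 2L != 0L || length(a) < length(flt$h))
      stop("signal too short for requested decomposition level")
    st <- dwt_step(a, flt)
    details[[j]] <- st$detail
    a <- st$approx
  }
  list(approx = a, details = details)
}

idwt_multilevel <- function(dec, flt) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details)))
    a <- idwt_step(a, dec$details[[j]], flt)
  a
}

# symmetric (reflect, no repeat of edge point) right padding to a multiple
# of 2^level
pad_symmetric <- function(x, level) {
  n <- length(x)
  block <- 2L^level
  target <- ceiling(n / block) * block
  extra <- target - n
  if (extra == 0L) return(x)
  if (extra > n - 1L)
    stop("signal too short to pad for requested level")
  c(x, x[seq(n - 1L, by = -1L, length.out = extra)])
}

#' Wavelet denoising by universal soft thresholding
#'
#' Multilevel periodized orthogonal wavelet decomposition (haar or db4),
#' soft thresholding of all detail coefficients at the universal
#' threshold `sigma * sqrt(2 log n)` with `sigma` estimated from the
#' median absolute deviation of the finest-level details, and
#' reconstruction truncated to the original length.
#'
#' @param x numeric signal (or a `raman_spectrum`; see
#'   [wavelet_denoise()]).
#' @param family `"db4"` (default) or `"haar"`.
#' @param level decomposition depth (default 4).
#' @return denoised numeric vector, same length as `x`.
#' @export
wavelet_denoise_vector <- function(x, family = c("db4", "haar"), level = 4) {
  family <- match.arg(family)
  stopifnot(level >= 1)
  flt <- wavelet_filters(family)
  n0 <- length(x)
  xp <- pad_symmetric(x, level)
  dec <- dwt_multilevel(xp, flt, level)
  sigma <- stats::mad(dec$details[[1]], center = 0)
  thr <- sigma * sqrt(2 * log(length(xp)))
  dec$details <- lapply(dec$details, function(d)
    sign(d) * pmax(abs(d) - thr, 0))
  idwt_multilevel(dec, flt)[seq_len(n0)]
}
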