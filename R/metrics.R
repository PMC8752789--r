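# Image- and estimate-quality metrics: MSE, PSNR, SSIM, VIF, R^2 and
# the relative-improvement arithmetic used to compare methods.

# 2-d Gaussian kernel, unit sum.
.gaussKernel <- function(size, sigma) {
  r <- (size - 1) / 2
  x <- seq(-r, r)
  k1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

# Windowed filtering with replicated edges: pad explicitly (so images
# smaller than the window work too), filter, crop back.
.winFilter <- function(x, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  n1 <- nrow(x); n2 <- ncol(x)
  ri <- pmin(pmax(seq(1 - r, n1 + r), 1), n1)
  ci <- pmin(pmax(seq(1 - r, n2 + r), 1), n2)
  xp <- x[ri, ci, drop = FALSE]
  fp <- EBImage::filter2(xp, kern, boundary = "circular")
  fp[(r + 1):(r + n1), (r + 1):(r + n2), drop = FALSE]
}

#' Per-pixel squared error map and its mean
#'
#' @param est,truth numeric matrices of equal shape (lifetime maps, ns).
#' @param mask optional logical matrix; TRUE pixels are excluded
#'   (failed pixels).
#' @return list with `map` (squared error, excluded pixels NA) and
#'   `mean` (mean squared error over included pixels, ns^2).
#' @export
mseMap <- function(est, truth, mask = NULL) {
  if (!all(dim(est) == dim(truth)))
    stop("shape mismatch between estimate and truth")
  m <- (est - truth)^2
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(est)))
      stop("shape mismatch between mask and images")
    m[mask] <- NA_real_
  }
  list(map = m, mean = mean(m, na.rm = TRUE))
}

#' Peak signal-to-noise ratio (dB)
#'
#' @param est,ref numeric matrices of equal shape.
#' @param data_range dynamic range L; defaults to the range of `ref`.
#' @return PSNR in dB (Inf for identical images).
#' @export
psnr <- function(est, ref, data_range = diff(range(ref))) {
  if (!all(dim(est) == dim(ref))) stop("shape mismatch")
  mse <- mean((est - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index (SSIM)
#'
#' Standard windowed SSIM with an 11 x 11 Gaussian window (sigma 1.5)
#' and stabilization constants `C1 = (k1 L)^2`, `C2 = (k2 L)^2`.
#' Symmetric in its two arguments.
#'
#' @param a,b numeric matrices of equal shape.
#' @param window window size (odd, default 11).
#' @param sigma Gaussian window sigma (default 1.5).
#' @param k1,k2 stabilization coefficients (defaults 0.01, 0.03).
#' @param data_range dynamic range L; defaults to the joint range of
#'   both images (1 when both are constant).
#' @param full return the per-pixel SSIM map as well.
#' @return mean SSIM, or `list(mean, map)` when `full = TRUE`.
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 data_range = NULL, full = FALSE) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("images must be finite")
  if (is.null(data_range)) {
    data_range <- diff(range(c(a, b)))
    if (data_range == 0) data_range <- 1
  }
  C1 <- (k1 * data_range)^2
  C2 <- (k2 * data_range)^2
  kern <- .gaussKernel(window, sigma)
  mu_a <- .winFilter(a, kern)
  mu_b <- .winFilter(b, kern)
  va <- .winFilter(a * a, kern) - mu_a^2
  vb <- .winFilter(b * b, kern) - mu_b^2
  cab <- .winFilter(a * b, kern) - mu_a * mu_b
  map <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  if (full) list(mean = mean(map), map = map) else mean(map)
}

#' Visual information fidelity (pixel-domain variant)
#'
#' Gaussian-scale-mixture VIF computed in the pixel domain over a
#' 4-level Gaussian pyramid (the commonly used `vifp` variant).
#' `vif(a, a) = 1`; heavier distortion of `b` lowers the score.
#'
#' @param a reference image (matrix).
#' @param b distorted image (matrix, same shape).
#' @param sigma_nsq visual noise variance (default 2).
#' @return VIF score (unitless, >= 0).
#' @export
vif <- function(a, b, sigma_nsq = 2) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (stats::sd(a) == 0)
    stop("degenerate zero-variance reference image")
  ref <- a; dist <- b
  num <- 0; den <- 0
  eps <- 1e-10
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    kern <- .gaussKernel(N, N / 5)
    if (scale > 1) {
      ref <- .winFilter(ref, kern)
      dist <- .winFilter(dist, kern)
      ri <- seq(1, nrow(ref), by = 2)
      ci <- seq(1, ncol(ref), by = 2)
      ref <- ref[ri, ci, drop = FALSE]
      dist <- dist[ri, ci, drop = FALSE]
    }
    if (nrow(ref) < N || ncol(ref) < N) break
    mu1 <- .winFilter(ref, kern)
    mu2 <- .winFilter(dist, kern)
    s1 <- pmax(.winFilter(ref * ref, kern) - mu1^2, 0)
    s2 <- pmax(.winFilter(dist * dist, kern) - mu2^2, 0)
    s12 <- .winFilter(ref * dist, kern) - mu1 * mu2
    g <- s12 / (s1 + eps)
    sv <- s2 - g * s12
    g[s1 < eps] <- 0
    sv[s1 < eps] <- s2[s1 < eps]
    sv[sv < eps] <- eps
    g[s2 < eps] <- 0
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  if (den == 0) stop("reference carries no information at any scale")
  num / den
}

#' Relative improvement of one score over another
#'
#' Formalizes "x% more similar" / "k-fold higher" comparisons as
#' `(x - y) / y`.
#'
#' @param x,y scores; `y` must be positive.
#' @param as `"ratio"` (raw `(x-y)/y`), `"percent"` (times 100), or
#'   `"fold"` (same ratio, conventionally read as "k-fold higher").
#' @return numeric.
#' @examples
#' relativeImprovement(0.88, 0.51, "percent")  # ~72.5 -> "73% more"
#' relativeImprovement(0.22, 0.09, "fold")     # ~1.44-fold higher
#' @export
relativeImprovement <- function(x, y, as = c("ratio", "percent", "fold")) {
  as <- match.arg(as)
  if (!is.finite(y) || y <= 0) stop("reference score y must be positive")
  r <- (x - y) / y
  switch(as, ratio = r, percent = 100 * r, fold = r)
}

#' Coefficient of determination against the identity line
#'
#' `1 - SS_res / SS_tot` of `est_b` against `est_a`, with residuals
#' taken about the identity line (not a fitted regression), measuring
#' consistency of two estimates of the same quantity. Ranges from
#' -Inf to 1.
#'
#' @param est_a reference estimates (the abscissa).
#' @param est_b comparison estimates.
#' @return numeric R^2 (can be negative).
#' @export
rSquared <- function(est_a, est_b) {
  if (length(est_a) != length(est_b) || length(est_a) < 2)
    stop("inputs must have equal length >= 2")
  ok <- is.finite(est_a) & is.finite(est_b)
  a <- est_a[ok]; b <- est_b[ok]
  sstot <- sum((a - mean(a))^2)
  if (sstot == 0) stop("zero total variance in reference estimates")
  1 - sum((b - a)^2) / sstot
}

#' Full quality report between two lifetime maps
#'
#' @param est,ref numeric matrices of equal shape.
#' @param mask optional logical matrix of excluded pixels.
#' @return list with `mse`, `psnr`, `ssim`, `vif`, `r_squared`. `vif`
#'   is NA for images smaller than its coarsest analysis window.
#' @export
qualityReport <- function(est, ref, mask = NULL) {
  mm <- mseMap(est, ref, mask)
  list(mse = mm$mean,
       psnr = psnr(est, ref),
       ssim = ssim(est, ref),
       vif = tryCatch(vif(ref, est), error = function(e) NA_real_),
       r_squared = rSquared(as.vector(ref), as.vector(est)))
}
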