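# Decay-model simulation: IRFs, model pmfs, photon sampling, training
# libraries and synthetic benchmark images.

# Evaluate an expression under a temporary seed, restoring RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

#' Synthetic Gaussian instrument response function
#'
#' Builds a Gaussian IRF of given full width at half maximum centered at
#' `onset`, wrapped periodically onto the grid. A sub-bin (oversampled)
#' mass representation is kept alongside the per-bin weights so that
#' model convolution is accurate to well below the per-bin scale.
#'
#' @param grid a [HistogramGrid-class].
#' @param fwhm full width at half maximum in ns; must satisfy
#'   `0 < fwhm < period/4`.
#' @param onset center of the pulse in ns; `0 <= onset < period`.
#' @param oversample sub-bins per bin (default 32).
#' @return an [InstrumentResponse-class] with unit-sum weights whose mode
#'   is the bin containing `onset`.
#' @examples
#' irf <- gaussianIRF(histogramGrid(), fwhm = 0.5, onset = 5)
#' which.max(irfWeights(irf))  # bin containing t = 5 ns
#' @export
gaussianIRF <- function(grid = histogramGrid(), fwhm = 0.5, onset = 5,
                        oversample = 32L) {
  if (!is.finite(fwhm) || fwhm <= 0 || fwhm >= period(grid) / 4)
    stop(sprintf("fwhm must satisfy 0 < fwhm < period/4 = %.4g ns",
                 period(grid) / 4))
  if (!is.finite(onset) || onset < 0 || onset >= period(grid))
    stop(sprintf("onset must satisfy 0 <= onset < period = %.4g ns",
                 period(grid)))
  os <- as.integer(oversample)
  M <- nBins(grid) * os
  ws <- period(grid) / M
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  # mass attributed to sub-bin edge positions j*ws, integrated over the
  # centered window [(j-1/2)ws, (j+1/2)ws): keeps the IRF centroid
  # unbiased so convolution with the edge-integrated exponential masses
  # carries no systematic half-bin shift.
  edges <- ((0:M) - 0.5) * ws
  mass <- numeric(M)
  for (j in -1:1) {   # periodic wrap; fwhm < period/4 makes +/-1 ample
    z <- (edges - onset - j * period(grid)) / sigma
    mass <- mass + diff(stats::pnorm(z))
  }
  mass <- pmax(mass, 0)
  mass <- mass / sum(mass)
  w <- colSums(matrix(mass, nrow = os))
  new("InstrumentResponse", grid = grid, weights = w / sum(w),
      fine_weights = mass, oversample = os,
      fwhm = as.numeric(fwhm), onset = as.numeric(onset))
}

#' Idealized delta-function IRF
#'
#' All mass in the single sub-bin containing `onset`; the degenerate
#' zero-width limit of [gaussianIRF()].
#'
#' @inheritParams gaussianIRF
#' @return an [InstrumentResponse-class].
#' @export
deltaIRF <- function(grid = histogramGrid(), onset = 0, oversample = 32L) {
  if (!is.finite(onset) || onset < 0 || onset >= period(grid))
    stop(sprintf("onset must satisfy 0 <= onset < period = %.4g ns",
                 period(grid)))
  os <- as.integer(oversample)
  M <- nBins(grid) * os
  ws <- period(grid) / M
  mass <- numeric(M)
  mass[(as.integer(round(onset / ws)) %% M) + 1L] <- 1
  w <- colSums(matrix(mass, nrow = os))
  new("InstrumentResponse", grid = grid, weights = w, fine_weights = mass,
      oversample = os, fwhm = 0, onset = as.numeric(onset))
}

#' Wrap measured per-bin IRF weights into an InstrumentResponse
#'
#' Bin masses are spread uniformly over sub-bins; use this for IRFs that
#' are only known at bin resolution.
#'
#' @param weights non-negative per-bin weights (normalized internally).
#' @inheritParams gaussianIRF
#' @return an [InstrumentResponse-class].
#' @export
irfFromWeights <- function(weights, grid = histogramGrid(),
                           oversample = 32L) {
  if (length(weights) != nBins(grid))
    stop("weights must have one entry per grid bin")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  os <- as.integer(oversample)
  w <- weights / sum(weights)
  mass <- rep(w / os, each = os)
  new("InstrumentResponse", grid = grid, weights = w, fine_weights = mass,
      oversample = os, fwhm = NA_real_,
      onset = binCenters(grid)[which.max(w)])
}

# Exponential model masses at sub-bin edge positions: the exact
# integral of exp(-t/tau) over [j ws, (j+1) ws), amplitude-true across
# components (includes the tau factor; total mass tau (1 - exp(-T/tau))).
.expMasses <- function(tau, M, ws) {
  t0 <- (0:(M - 1)) * ws
  tau * exp(-t0 / tau) * (1 - exp(-ws / tau))
}

# Circular convolution via FFT of two equal-length mass vectors.
.circConv <- function(a, b_fft) {
  Re(stats::fft(stats::fft(a) * b_fft, inverse = TRUE)) / length(a)
}

#' Model decay pmf: bi-exponential convolved with the IRF
#'
#' Computes the probability mass function over time bins of a one- or
#' two-component exponential decay under periodic (repetitive pulsed)
#' excitation, as the circular convolution of the model
#' `m(t) = alpha1 exp(-t/tau1) + (1 - alpha1) exp(-t/tau2)` with the
#' instrument response. The convolution is carried out on the IRF's
#' oversampled sub-bin grid with analytically bin-integrated exponential
#' masses, then folded back to the histogram bins, so discretization
#' error is far below the per-bin probability scale.
#'
#' @param params a [LifetimeParams-class] (any length).
#' @param irf an [InstrumentResponse-class].
#' @param grid optional grid the output must live on; must equal the
#'   IRF's grid (a mismatch is an error).
#' @param wrap logical; `TRUE` (default) wraps the incomplete decay
#'   periodically (circular convolution), `FALSE` truncates at the end
#'   of the period instead.
#' @return a numeric probability vector over bins (length-1 `params`),
#'   or a matrix with one row per parameter triple. Rows sum to 1.
#' @examples
#' p <- decayPmf(lifetimeParams(1, 2, 2), deltaIRF(onset = 0))
#' sum(p)  # 1
#' @export
decayPmf <- function(params, irf, grid = NULL, wrap = TRUE) {
  stopifnot(is(params, "LifetimeParams"), is(irf, "InstrumentResponse"))
  if (!is.null(grid) &&
      (nBins(grid) != nBins(irf) ||
       abs(period(grid) - period(irf)) > 1e-12))
    stop("grid mismatch: requested output grid differs from the IRF grid")
  os <- irf@oversample
  nb <- nBins(irf)
  M <- nb * os
  ws <- period(irf) / M
  n <- length(params)
  if (wrap) {
    irf_fft <- stats::fft(irf@fine_weights)
  } else {
    pad <- c(irf@fine_weights, numeric(M))
    irf_fft <- stats::fft(pad)
  }
  out <- matrix(0, n, nb)
  for (i in seq_len(n)) {
    m <- params@alpha1[i] * .expMasses(params@tau1[i], M, ws) +
      (1 - params@alpha1[i]) * .expMasses(params@tau2[i], M, ws)
    if (wrap) {
      cv <- .circConv(m, irf_fft)
    } else {
      cv <- (Re(stats::fft(stats::fft(c(m, numeric(M))) * irf_fft,
                           inverse = TRUE)) / (2 * M))[1:M]
    }
    cv <- pmax(cv, 0)
    p <- colSums(matrix(cv, nrow = os))
    out[i, ] <- p / sum(p)
  }
  if (n == 1L) drop(out) else out
}

#' Photon-sampled (degraded) decay histogram
#'
#' Simulates the photon collection process: the total photon count is
#' Poisson with mean `rate` (or fixed when `total` is given), and counts
#' are distributed over bins multinomially according to `pmf`.
#'
#' @param pmf a probability vector over bins (must sum to 1).
#' @param rate expected photons per pixel (> 0).
#' @param grid the [HistogramGrid-class] the pmf lives on.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param total optional fixed total photon count, bypassing the Poisson
#'   draw (variance-controlled mode).
#' @return a [DecayHistogram-class] whose counts sum to the drawn total.
#' @export
sampleDecay <- function(pmf, rate, grid = histogramGrid(), seed = NULL,
                        total = NULL) {
  if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-6)
    stop("pmf must be a non-negative vector summing to 1")
  if (is.null(total) && (!is.finite(rate) || rate <= 0))
    stop("rate must be positive")
  if (length(pmf) != nBins(grid))
    stop("pmf length must equal the grid bin count")
  .withSeed(seed, {
    n <- if (is.null(total)) stats::rpois(1, rate) else as.integer(total)
    cnt <- if (n > 0L) as.integer(stats::rmultinom(1, n, pmf))
           else integer(length(pmf))
    decayHistogram(cnt, grid = grid, rate = as.numeric(rate))
  })
}

#' Build a paired ground-truth / degraded-decay training library
#'
#' Takes the outer product of the parameter grids, discards combinations
#' violating the canonical order `tau1 <= tau2`, optionally thins the
#' retained set to a target size, computes one model pmf per retained
#' triple, and samples `per_truth` degraded decays per pmf at emission
#' rates cycled from `rates`. Deterministic for a fixed seed.
#'
#' The default grids span the instrument-typical lifetime range
#' (tau1 0.1-5 ns, tau2 0.5-10 ns, alpha1 0-1 in steps of 0.1, rates
#' from 50 to 1500 photons/pixel), thinned to about 600 ground truths.
#'
#' @param irf an [InstrumentResponse-class].
#' @param alpha_grid,tau1_grid,tau2_grid parameter grids.
#' @param rates emission rates cycled over the degraded draws per truth.
#' @param per_truth degraded decays per ground truth.
#' @param thin_to approximate number of retained combinations (NULL to
#'   keep all).
#' @param seed integer seed.
#' @return a [TrainingLibrary-class].
#' @export
buildTrainingLibrary <- function(irf,
                                 alpha_grid = seq(0, 1, by = 0.1),
                                 tau1_grid = seq(0.1, 5, length.out = 10),
                                 tau2_grid = seq(0.5, 10, length.out = 10),
                                 rates = c(50, 100, 150, 300, 600, 1500),
                                 per_truth = 500L,
                                 thin_to = 600L,
                                 seed = 1L) {
  if (!length(alpha_grid) || !length(tau1_grid) || !length(tau2_grid))
    stop("parameter grids must be non-empty")
  combos <- expand.grid(alpha1 = alpha_grid, tau1 = tau1_grid,
                        tau2 = tau2_grid, KEEP.OUT.ATTRS = FALSE)
  combos <- combos[combos$tau1 <= combos$tau2, , drop = FALSE]
  if (!nrow(combos))
    stop("no parameter combinations retained (tau1 <= tau2 filter)")
  if (!is.null(thin_to) && nrow(combos) > thin_to) {
    keep <- unique(round(seq(1, nrow(combos), length.out = thin_to)))
    combos <- combos[keep, , drop = FALSE]
  }
  truth <- lifetimeParams(combos$alpha1, combos$tau1, combos$tau2)
  pmfs <- decayPmf(truth, irf)
  if (is.null(dim(pmfs))) pmfs <- matrix(pmfs, nrow = 1)
  n_truth <- length(truth)
  n_deg <- n_truth * as.integer(per_truth)
  parent <- rep(seq_len(n_truth), each = per_truth)
  rate_vec <- rates[((seq_len(per_truth) - 1L) %% length(rates)) + 1L]
  rate_all <- rep(rate_vec, times = n_truth)
  degraded <- matrix(0L, n_deg, nBins(irf))
  .withSeed(seed, {
    for (k in seq_len(n_deg)) {
      n <- stats::rpois(1, rate_all[k])
      if (n > 0L)
        degraded[k, ] <- as.integer(stats::rmultinom(1, n, pmfs[parent[k], ]))
    }
  })
  new("TrainingLibrary", irf = irf, truth = truth, pmfs = pmfs,
      degraded = degraded, parent = parent, rates = rate_all,
      seed = as.integer(seed))
}

#' Simulate a benchmark FLIM image with known ground truth
#'
#' Samples one decay histogram per pixel from the model pmf of that
#' pixel's parameter triple and attaches the truth map to the cube.
#'
#' @param pattern a list with H x W numeric matrices `alpha1`, `tau1`,
#'   `tau2` (the per-pixel ground truth), or a length-H*W
#'   [LifetimeParams-class] with a `dim` attribute supplied via
#'   `pattern_dim`.
#' @param rate expected photons per pixel.
#' @param irf an [InstrumentResponse-class].
#' @param seed integer seed.
#' @param total optional fixed per-pixel photon count.
#' @param pattern_dim c(H, W) when `pattern` is a LifetimeParams.
#' @return a [DecayCube-class] with truth attached.
#' @export
simulateBenchmarkImage <- function(pattern, rate, irf, seed = NULL,
                                   total = NULL, pattern_dim = NULL) {
  if (is(pattern, "LifetimeParams")) {
    stopifnot(!is.null(pattern_dim), length(pattern) == prod(pattern_dim))
    truth <- pattern
    h <- pattern_dim[1]; w <- pattern_dim[2]
  } else {
    h <- nrow(pattern$alpha1); w <- ncol(pattern$alpha1)
    truth <- lifetimeParams(as.vector(pattern$alpha1),
                            as.vector(pattern$tau1),
                            as.vector(pattern$tau2))
  }
  key <- paste(truth@alpha1, truth@tau1, truth@tau2)
  uniq <- !duplicated(key)
  upmf <- decayPmf(truth[which(uniq)], irf)
  if (is.null(dim(upmf))) upmf <- matrix(upmf, nrow = 1)
  idx <- match(key, key[uniq])
  nb <- nBins(irf)
  cube <- array(0L, dim = c(h, w, nb))
  .withSeed(seed, {
    for (p in seq_len(h * w)) {
      n <- if (is.null(total)) stats::rpois(1, rate) else as.integer(total)
      if (n > 0L) {
        i <- ((p - 1L) %% h) + 1L
        j <- ((p - 1L) %/% h) + 1L
        cube[i, j, ] <- as.integer(stats::rmultinom(1, n, upmf[idx[p], ]))
      }
    }
  })
  decayCube(cube, grid = decayGrid(irf), truth = truth,
            rate = as.numeric(rate))
}

# 7x5 block-letter bitmaps used by glyphPattern.
.glyphFont <- function() {
  list(
    F = c("11111", "10000", "10000", "11110", "10000", "10000", "10000"),
    L = c("10000", "10000", "10000", "10000", "10000", "10000", "11111"),
    I = c("11111", "00100", "00100", "00100", "00100", "00100", "11111"),
    M = c("10001", "11011", "10101", "10101", "10001", "10001", "10001"))
}

#' Deterministic two-lifetime glyph test pattern
#'
#' A stand-in benchmark layout: block letters ("FLIM") rendered with a
#' foreground parameter triple on a background triple. Used to test
#' contrast recovery of image estimators; the layout is deterministic.
#'
#' @param height,width image size in pixels (defaults 14 x 47).
#' @param fg,bg [LifetimeParams-class] of length 1 for letter and
#'   background pixels.
#' @return list of H x W matrices `alpha1`, `tau1`, `tau2` plus a
#'   logical `mask` of foreground pixels.
#' @export
glyphPattern <- function(height = 14L, width = 47L,
                         fg = lifetimeParams(0.5, 1.5, 3.5),
                         bg = lifetimeParams(0.8, 1.0, 3.0)) {
  stopifnot(length(fg) == 1L, length(bg) == 1L, height >= 9L, width >= 26L)
  mask <- matrix(FALSE, height, width)
  font <- .glyphFont()
  row0 <- max(1L, (height - 7L) %/% 2L)
  col <- max(2L, (width - (length(font) * 6L - 1L)) %/% 2L)
  for (ch in names(font)) {
    bits <- font[[ch]]
    for (r in 1:7) {
      on <- which(strsplit(bits[r], "")[[1]] == "1")
      mask[row0 + r - 1L, col + on - 1L] <- TRUE
    }
    col <- col + 6L
  }
  pick <- function(a, b) ifelse(mask, a, b)
  list(alpha1 = pick(fg@alpha1, bg@alpha1),
       tau1 = pick(fg@tau1, bg@tau1),
       tau2 = pick(fg@tau2, bg@tau2),
       mask = mask)
}

#' Amplitude fraction of a two-dye mixture
#'
#' Photon-contribution fraction of dye 1 given molar concentrations and
#' relative brightnesses: `alpha1 = c1 b1 / (c1 b1 + c2 b2)`. Symmetric:
#' swapping the dyes maps alpha1 to 1 - alpha1.
#'
#' @param conc1,conc2 molar concentrations (> 0).
#' @param brightness1,brightness2 relative brightnesses (> 0).
#' @return the amplitude fraction of dye 1, in (0, 1).
#' @examples
#' mixtureAlpha(1, 1, 1, 1)  # 0.5
#' @export
mixtureAlpha <- function(conc1, brightness1, conc2, brightness2) {
  vals <- c(conc1, brightness1, conc2, brightness2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("concentrations and brightnesses must be positive")
  conc1 * brightness1 / (conc1 * brightness1 + conc2 * brightness2)
}
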