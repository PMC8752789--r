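# Constructors, accessors and show methods for the core containers.

#' Create a histogram grid
#'
#' @param n_bins number of time bins (default 256).
#' @param period laser repetition period in ns (default 50, i.e. 20 MHz).
#' @return a [HistogramGrid-class].
#' @examples
#' g <- histogramGrid()
#' binWidth(g)
#' @export
histogramGrid <- function(n_bins = 256L, period = 50) {
  new("HistogramGrid", n_bins = as.integer(n_bins), period = as.numeric(period))
}

#' @describeIn histogramGrid number of bins
#' @param x a HistogramGrid (or object carrying one).
#' @export
setMethod("nBins", "HistogramGrid", function(x) x@n_bins)
#' @export
setMethod("period", "HistogramGrid", function(x) x@period)
#' @export
setMethod("binWidth", "HistogramGrid", function(x) x@period / x@n_bins)
#' @export
setMethod("binCenters", "HistogramGrid", function(x) {
  w <- binWidth(x)
  (seq_len(x@n_bins) - 0.5) * w
})

setMethod("show", "HistogramGrid", function(object) {
  cat(sprintf("HistogramGrid: %d bins over %.4g ns (bin width %.4g ns)\n",
              object@n_bins, object@period, binWidth(object)))
})

#' Extract the grid of an object
#'
#' @param x an object with a `grid` slot.
#' @return a [HistogramGrid-class].
#' @export
decayGrid <- function(x) {
  stopifnot(.hasSlot(x, "grid"))
  x@grid
}

#' @export
setMethod("nBins", "ANY", function(x) nBins(decayGrid(x)))
#' @export
setMethod("period", "ANY", function(x) period(decayGrid(x)))
#' @export
setMethod("binWidth", "ANY", function(x) binWidth(decayGrid(x)))
#' @export
setMethod("binCenters", "ANY", function(x) binCenters(decayGrid(x)))

#' IRF per-bin weights
#' @param x an [InstrumentResponse-class].
#' @return numeric vector summing to 1.
#' @export
irfWeights <- function(x) {
  stopifnot(is(x, "InstrumentResponse"))
  x@weights
}

setMethod("show", "InstrumentResponse", function(object) {
  cat(sprintf(
    "InstrumentResponse on %d bins / %.4g ns; fwhm %.3g ns; onset %.3g ns; mode at bin %d\n",
    nBins(object), period(object), object@fwhm, object@onset,
    which.max(object@weights)))
})

#' Construct (vectorized) lifetime parameter triples
#'
#' Canonicalizes the component order to `tau1 <= tau2`, swapping `alpha1`
#' for `1 - alpha1` where needed. Inputs are recycled to a common length.
#'
#' @param alpha1 amplitude fraction(s) of the short component, in [0, 1].
#' @param tau1,tau2 component lifetimes (ns), positive.
#' @return a [LifetimeParams-class].
#' @examples
#' p <- lifetimeParams(0.5, 0.6, 3.3)
#' apparentLifetime(p)  # 1.95 ns
#' @export
lifetimeParams <- function(alpha1, tau1, tau2) {
  n <- max(length(alpha1), length(tau1), length(tau2))
  alpha1 <- rep_len(as.numeric(alpha1), n)
  tau1 <- rep_len(as.numeric(tau1), n)
  tau2 <- rep_len(as.numeric(tau2), n)
  swap <- which(tau1 > tau2)
  if (length(swap)) {
    tmp <- tau1[swap]; tau1[swap] <- tau2[swap]; tau2[swap] <- tmp
    alpha1[swap] <- 1 - alpha1[swap]
  }
  alpha1 <- pmin(pmax(alpha1, 0), 1)
  new("LifetimeParams", alpha1 = alpha1, tau1 = tau1, tau2 = tau2)
}

#' @export
setMethod("alpha1", "LifetimeParams", function(x) x@alpha1)
#' @export
setMethod("tau1", "LifetimeParams", function(x) x@tau1)
#' @export
setMethod("tau2", "LifetimeParams", function(x) x@tau2)
#' @export
setMethod("apparentLifetime", "LifetimeParams", function(x, ...) {
  x@alpha1 * x@tau1 + (1 - x@alpha1) * x@tau2
})
#' @export
setMethod("length", "LifetimeParams", function(x) length(x@alpha1))

#' @export
setMethod("[", "LifetimeParams", function(x, i, j, ..., drop = TRUE) {
  new("LifetimeParams", alpha1 = x@alpha1[i], tau1 = x@tau1[i],
      tau2 = x@tau2[i])
})

setMethod("show", "LifetimeParams", function(object) {
  n <- length(object)
  cat(sprintf("LifetimeParams of length %d\n", n))
  if (n) {
    k <- min(n, 5L)
    df <- data.frame(alpha1 = object@alpha1[1:k], tau1 = object@tau1[1:k],
                     tau2 = object@tau2[1:k],
                     tau_apparent = apparentLifetime(object)[1:k])
    print(df, digits = 4)
    if (n > k) cat(sprintf("... and %d more\n", n - k))
  }
})

#' Coerce lifetime parameters to a data.frame
#' @param x a [LifetimeParams-class].
#' @param ... unused.
#' @return data.frame with alpha1, tau1, tau2, tau_apparent columns.
#' @export
as.data.frame.LifetimeParams <- function(x, ...) {
  data.frame(alpha1 = x@alpha1, tau1 = x@tau1, tau2 = x@tau2,
             tau_apparent = apparentLifetime(x))
}

#' Construct a decay histogram
#'
#' @param counts non-negative integer photon counts, one per bin.
#' @param grid a [HistogramGrid-class].
#' @param rate expected photons/pixel used in sampling (NA if unknown).
#' @return a [DecayHistogram-class].
#' @export
decayHistogram <- function(counts, grid = histogramGrid(), rate = NA_real_) {
  cnt <- as.integer(round(counts))
  new("DecayHistogram", grid = grid, counts = cnt, rate = as.numeric(rate))
}

#' @export
setMethod("counts", "DecayHistogram", function(object, ...) object@counts)
#' @export
setMethod("totalCounts", "DecayHistogram", function(x) sum(x@counts))

setMethod("show", "DecayHistogram", function(object) {
  cat(sprintf("DecayHistogram: %d photons over %d bins (rate %.4g)\n",
              totalCounts(object), nBins(object), object@rate))
})

#' Construct a decay cube (H x W image of decay histograms)
#'
#' @param counts integer array H x W x n_bins.
#' @param grid a [HistogramGrid-class].
#' @param truth optional [LifetimeParams-class] of length H*W.
#' @param rate nominal emission rate (photons/pixel).
#' @return a [DecayCube-class].
#' @export
decayCube <- function(counts, grid = histogramGrid(),
                      truth = lifetimeParams(numeric(0), numeric(0), numeric(0)),
                      rate = NA_real_) {
  storage.mode(counts) <- "integer"
  new("DecayCube", grid = grid, counts = counts, truth = truth,
      rate = as.numeric(rate))
}

#' @export
setMethod("counts", "DecayCube", function(object, ...) object@counts)
#' @export
setMethod("dim", "DecayCube", function(x) dim(x@counts)[1:2])
#' @export
setMethod("totalCounts", "DecayCube", function(x) {
  apply(x@counts, c(1, 2), sum)
})
#' @export
setMethod("truthParams", "DecayCube", function(x) x@truth)

#' Extract one pixel of a cube as a DecayHistogram
#' @param cube a [DecayCube-class].
#' @param i,j pixel row and column.
#' @return a [DecayHistogram-class].
#' @export
cubePixel <- function(cube, i, j) {
  decayHistogram(cube@counts[i, j, ], grid = cube@grid, rate = cube@rate)
}

setMethod("show", "DecayCube", function(object) {
  d <- dim(object)
  cat(sprintf("DecayCube: %d x %d pixels, %d bins; truth %s; rate %.4g\n",
              d[1], d[2], nBins(object),
              if (length(object@truth)) "attached" else "absent",
              object@rate))
})

#' @export
setMethod("truthParams", "TrainingLibrary", function(x) x@truth)

setMethod("show", "TrainingLibrary", function(object) {
  cat(sprintf(
    "TrainingLibrary: %d ground-truth pmfs, %d degraded decays (rates %s; seed %d)\n",
    nrow(object@pmfs), nrow(object@degraded),
    paste(sort(unique(object@rates)), collapse = "/"), object@seed))
})

#' @export
setMethod("modulation", "PhasorPoint", function(x) sqrt(x@g^2 + x@s^2))
#' @export
setMethod("phase", "PhasorPoint", function(x) atan2(x@s, x@g))

setMethod("show", "PhasorPoint", function(object) {
  cat(sprintf(
    "PhasorPoint (n = %d, omega = %.4g rad/ns): g = %.4f, s = %.4f, m = %.4f, phi = %.4f\n",
    object@harmonic, object@omega, object@g, object@s,
    modulation(object), phase(object)))
})

#' @export
setMethod("fitParams", "FitResult", function(x) x@params)
#' @export
setMethod("apparentLifetime", "FitResult", function(x, ...) {
  apparentLifetime(x@params)
})

setMethod("show", "FitResult", function(object) {
  p <- object@params
  cat(sprintf(
    "FitResult [%s]: alpha1 = %.3f, tau1 = %.3f, tau2 = %.3f (tau_a = %.3f ns)\n  objective = %.6g, converged = %s, failed = %s, %d evals\n",
    object@method, p@alpha1, p@tau1, p@tau2, apparentLifetime(p),
    object@objective, object@converged, object@failed, object@n_iter))
})

setMethod("show", "NetworkBundle", function(object) {
  cat(sprintf(
    "NetworkBundle [stage: %s] on %d bins; tau_scale %.3g ns; IRF %s\n",
    object@stage, nBins(object@grid), object@tau_scale,
    substr(object@irf_fingerprint, 1, 8)))
})

setMethod("show", "AlignmentReport", function(object) {
  cat(sprintf(
    "AlignmentReport: shift %+d bins; CoM %.4f -> %.4f ns (reference %.4f ns)\n",
    object@shift_bins, object@com_before, object@com_after,
    object@reference_com))
})

#' Serialize an alignment report to JSON
#' @param report an [AlignmentReport-class].
#' @return a JSON string.
#' @export
alignmentReportJSON <- function(report) {
  jsonlite::toJSON(list(shift_bins = report@shift_bins,
                        com_before = report@com_before,
                        com_after = report@com_after,
                        reference_com = report@reference_com),
                   auto_unbox = TRUE, digits = NA)
}
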