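#' @import methods
#' @importFrom stats fft rpois rmultinom rnorm runif optim sd ks.test
#'   quantile median coef resid fitted approx setNames complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

#' HistogramGrid: the shared time axis of all decay histograms
#'
#' A `HistogramGrid` fixes the discretization every decay, IRF and model
#' pmf lives on: the number of time bins and the laser repetition period.
#' The default instrument configuration is 256 bins over a 50 ns period
#' (20 MHz pulsed excitation).
#'
#' @slot n_bins integer, number of time bins (>= 2).
#' @slot period numeric, laser repetition period in ns.
#' @export
setClass("HistogramGrid",
  representation(n_bins = "integer", period = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@n_bins) != 1L || is.na(object@n_bins) ||
        object@n_bins < 2L)
      msg <- c(msg, "n_bins must be a single integer >= 2")
    if (length(object@period) != 1L || !is.finite(object@period) ||
        object@period <= 0)
      msg <- c(msg, "period must be a single positive number (ns)")
    if (is.null(msg)) TRUE else msg
  })

#' InstrumentResponse: the temporal response of the detection chain
#'
#' Per-bin IRF weights (unit sum) plus an oversampled sub-bin
#' representation used for accurate convolution with decay models.
#'
#' @slot grid a [HistogramGrid-class].
#' @slot weights numeric vector, one non-negative weight per bin, sum 1.
#' @slot fine_weights numeric vector of length `n_bins * oversample`,
#'   sub-bin masses, sum 1.
#' @slot oversample integer sub-bins per bin.
#' @slot fwhm numeric, full width at half maximum in ns (NA if unknown).
#' @slot onset numeric, nominal onset position in ns (NA if unknown).
#' @export
setClass("InstrumentResponse",
  representation(grid = "HistogramGrid", weights = "numeric",
                 fine_weights = "numeric", oversample = "integer",
                 fwhm = "numeric", onset = "numeric"),
  validity = function(object) {
    msg <- NULL
    nb <- object@grid@n_bins
    if (length(object@weights) != nb)
      msg <- c(msg, sprintf("weights must have length n_bins = %d", nb))
    if (any(object@weights < -1e-12))
      msg <- c(msg, "weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "weights must sum to 1")
    if (length(object@fine_weights) != nb * object@oversample)
      msg <- c(msg, "fine_weights must have length n_bins * oversample")
    if (abs(sum(object@fine_weights) - 1) > 1e-8)
      msg <- c(msg, "fine_weights must sum to 1")
    if (is.null(msg)) TRUE else msg
  })

#' LifetimeParams: vectorized bi-exponential decay parameters
#'
#' Parameter triples (alpha1, tau1, tau2) of the two-component decay model
#' m(t) = alpha1 exp(-t/tau1) + (1 - alpha1) exp(-t/tau2). Construction
#' canonicalizes the component order to tau1 <= tau2 (swapping alpha1 for
#' 1 - alpha1 when needed) to remove label-switching ambiguity. The class
#' is vectorized: one object holds any number of triples.
#'
#' @slot alpha1 numeric in [0, 1], amplitude fraction of the short
#'   component.
#' @slot tau1 numeric > 0, short lifetime (ns).
#' @slot tau2 numeric > 0, long lifetime (ns), tau1 <= tau2.
#' @export
setClass("LifetimeParams",
  representation(alpha1 = "numeric", tau1 = "numeric", tau2 = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@alpha1)
    if (length(object@tau1) != n || length(object@tau2) != n)
      msg <- c(msg, "alpha1, tau1, tau2 must have equal length")
    if (any(!is.finite(object@alpha1)) ||
        any(object@alpha1 < -1e-12) || any(object@alpha1 > 1 + 1e-12))
      msg <- c(msg, "alpha1 must lie in [0, 1]")
    if (any(!is.finite(object@tau1)) || any(object@tau1 <= 0) ||
        any(!is.finite(object@tau2)) || any(object@tau2 <= 0))
      msg <- c(msg, "tau1 and tau2 must be positive")
    if (any(object@tau1 > object@tau2 + 1e-12))
      msg <- c(msg, "canonical ordering requires tau1 <= tau2")
    if (is.null(msg)) TRUE else msg
  })

#' DecayHistogram: photon counts per time bin for one pixel
#'
#' @slot grid a [HistogramGrid-class].
#' @slot counts integer vector of non-negative per-bin photon counts.
#' @slot rate numeric, expected photons per pixel used when sampling
#'   (NA for measured data).
#' @export
setClass("DecayHistogram",
  representation(grid = "HistogramGrid", counts = "integer",
                 rate = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@counts) != object@grid@n_bins)
      msg <- c(msg, "counts length must equal n_bins")
    if (any(is.na(object@counts)) || any(object@counts < 0L))
      msg <- c(msg, "counts must be non-negative integers")
    if (is.null(msg)) TRUE else msg
  })

#' DecayCube: an H x W image of decay histograms
#'
#' Per-pixel photon counts stored as an H x W x n_bins integer array,
#' optionally with the ground-truth per-pixel decay parameters attached.
#'
#' @slot grid a [HistogramGrid-class].
#' @slot counts integer array, dim H x W x n_bins.
#' @slot truth a [LifetimeParams-class] of length H*W (row-major by
#'   column, i.e. `matrix` order), or of length 0 when unknown.
#' @slot rate numeric, nominal emission rate (photons/pixel; NA unknown).
#' @export
setClass("DecayCube",
  representation(grid = "HistogramGrid", counts = "array",
                 truth = "LifetimeParams", rate = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@counts)
    if (length(d) != 3L)
      msg <- c(msg, "counts must be a 3-d array (H x W x n_bins)")
    else {
      if (d[3] != object@grid@n_bins)
        msg <- c(msg, "third dimension of counts must equal n_bins")
      nt <- length(object@truth@alpha1)
      if (nt != 0L && nt != d[1] * d[2])
        msg <- c(msg, "truth must be empty or have one entry per pixel")
    }
    if (any(object@counts < 0L))
      msg <- c(msg, "counts must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' TrainingLibrary: paired ground-truth pmfs and degraded decays
#'
#' Ground-truth decay pmfs over a parameter grid, together with
#' photon-sampled (degraded) realizations used to train the adversarial
#' restoration networks.
#'
#' @slot irf the [InstrumentResponse-class] the library was built for.
#' @slot truth a [LifetimeParams-class], one triple per ground truth.
#' @slot pmfs numeric matrix (n_truth x n_bins), each row sums to 1.
#' @slot degraded integer matrix (n_degraded x n_bins) of sampled counts.
#' @slot parent integer vector mapping each degraded row to its truth row.
#' @slot rates numeric vector, emission rate of each degraded row.
#' @slot seed integer seed the library was generated with.
#' @export
setClass("TrainingLibrary",
  representation(irf = "InstrumentResponse", truth = "LifetimeParams",
                 pmfs = "matrix", degraded = "matrix",
                 parent = "integer", rates = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    nt <- nrow(object@pmfs)
    if (length(object@truth@alpha1) != nt)
      msg <- c(msg, "one parameter triple per pmf row required")
    if (nt > 0 && max(abs(rowSums(object@pmfs) - 1)) > 1e-8)
      msg <- c(msg, "every pmf row must sum to 1")
    if (nrow(object@degraded) != length(object@parent) ||
        nrow(object@degraded) != length(object@rates))
      msg <- c(msg, "degraded, parent and rates must agree in length")
    if (length(object@parent) &&
        (min(object@parent) < 1L || max(object@parent) > nt))
      msg <- c(msg, "parent indices must point at valid ground truths")
    if (is.null(msg)) TRUE else msg
  })

#' PhasorPoint: a decay's Fourier coordinates at one harmonic
#'
#' @slot harmonic positive integer harmonic number n.
#' @slot omega numeric angular frequency n * 2 * pi / period (rad/ns).
#' @slot g numeric, cosine (real) component.
#' @slot s numeric, sine (imaginary) component.
#' @export
setClass("PhasorPoint",
  representation(harmonic = "integer", omega = "numeric",
                 g = "numeric", s = "numeric"),
  validity = function(object) {
    if (length(object@harmonic) != 1L || object@harmonic < 1L)
      return("harmonic must be a positive integer")
    TRUE
  })

#' FitResult: outcome of a per-pixel lifetime fit
#'
#' @slot params [LifetimeParams-class] of length 1 (canonical order).
#' @slot objective numeric, the minimized objective (SSE or negative
#'   log-likelihood, depending on `method`).
#' @slot method character label ("td_lse", "td_mle", "dfd_lse", "gan").
#' @slot converged logical.
#' @slot n_iter integer, objective evaluations used.
#' @slot failed logical, TRUE when the estimate sits at the lifetime
#'   ceiling and the pixel should be masked.
#' @export
setClass("FitResult",
  representation(params = "LifetimeParams", objective = "numeric",
                 method = "character", converged = "logical",
                 n_iter = "integer", failed = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@params@alpha1) != 1L)
      msg <- c(msg, "params must hold exactly one triple")
    if (isTRUE(object@converged) && !is.finite(object@objective))
      msg <- c(msg, "a converged fit must have a finite objective")
    if (is.null(msg)) TRUE else msg
  })

#' NetworkBundle: the trained generator / critic / estimator stack
#'
#' Holds the three network specifications and their weights, the training
#' log, and a fingerprint of the IRF the bundle was trained for.
#' Inference refuses histograms carrying a different IRF unless
#' explicitly overridden, because the networks learn the IRF implicitly
#' and must be retrained when it changes.
#'
#' @slot g_spec,d_spec,e_spec lists describing the architectures.
#' @slot weights list of numeric arrays (opaque).
#' @slot training_log data.frame of per-iteration losses.
#' @slot irf_fingerprint character hash of the training IRF.
#' @slot grid the [HistogramGrid-class] the networks operate on.
#' @slot tau_scale numeric, lifetime (ns) that maps to 1.0 in the
#'   estimator's normalized output space.
#' @slot stage character, the latest completed training stage.
#' @export
setClass("NetworkBundle",
  representation(g_spec = "list", d_spec = "list", e_spec = "list",
                 weights = "list", training_log = "data.frame",
                 irf_fingerprint = "character", grid = "HistogramGrid",
                 tau_scale = "numeric", stage = "character"),
  validity = function(object) {
    if (length(object@tau_scale) != 1L || object@tau_scale <= 0)
      return("tau_scale must be a positive scalar")
    TRUE
  })

#' AlignmentReport: bookkeeping from CoME onset alignment
#'
#' @slot shift_bins signed integer circular shift that was applied.
#' @slot com_before,com_after numeric circular center of mass (ns).
#' @slot reference_com numeric target center of mass (ns).
#' @export
setClass("AlignmentReport",
  representation(shift_bins = "integer", com_before = "numeric",
                 com_after = "numeric", reference_com = "numeric"))
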