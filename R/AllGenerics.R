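#' @importFrom BiocGenerics counts
NULL

#' Number of time bins of an object's grid
#' @param x an object carrying a [HistogramGrid-class].
#' @return integer bin count.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Laser repetition period (ns)
#' @param x an object carrying a [HistogramGrid-class].
#' @return numeric period in ns.
#' @export
setGeneric("period", function(x) standardGeneric("period"))

#' Width of one time bin (ns)
#' @param x an object carrying a [HistogramGrid-class].
#' @return numeric bin width in ns.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' Bin-center time points (ns)
#' @param x an object carrying a [HistogramGrid-class].
#' @return numeric vector of bin centers, strictly increasing.
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' Amplitude fraction of the short lifetime component
#' @param x a [LifetimeParams-class] (or object containing one).
#' @return numeric vector in [0, 1].
#' @export
setGeneric("alpha1", function(x) standardGeneric("alpha1"))

#' Short lifetime component (ns)
#' @param x a [LifetimeParams-class] (or object containing one).
#' @return numeric vector.
#' @export
setGeneric("tau1", function(x) standardGeneric("tau1"))

#' Long lifetime component (ns)
#' @param x a [LifetimeParams-class] (or object containing one).
#' @return numeric vector.
#' @export
setGeneric("tau2", function(x) standardGeneric("tau2"))

#' Amplitude-weighted apparent lifetime (ns)
#'
#' The apparent lifetime of a two-component decay,
#' `tau_alpha = alpha1 * tau1 + (1 - alpha1) * tau2`: a convex
#' combination, always bounded by the two component lifetimes.
#'
#' @param x a [LifetimeParams-class], [FitResult-class], or anything with
#'   parameter accessors.
#' @param ... unused.
#' @return numeric vector of apparent lifetimes in ns.
#' @export
setGeneric("apparentLifetime",
           function(x, ...) standardGeneric("apparentLifetime"))

#' Total photon count
#' @param x a [DecayHistogram-class] or [DecayCube-class].
#' @return integer total (histogram) or H x W matrix (cube).
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' Modulation (radial) coordinate of a phasor
#' @param x a [PhasorPoint-class].
#' @return numeric sqrt(g^2 + s^2).
#' @export
setGeneric("modulation", function(x) standardGeneric("modulation"))

#' Phase angle of a phasor (radians)
#' @param x a [PhasorPoint-class].
#' @return numeric atan2(s, g).
#' @export
setGeneric("phase", function(x) standardGeneric("phase"))

#' Ground-truth parameters attached to an object
#' @param x a [DecayCube-class] or [TrainingLibrary-class].
#' @return a [LifetimeParams-class] (length 0 when absent).
#' @export
setGeneric("truthParams", function(x) standardGeneric("truthParams"))

#' Fitted parameters of a fit result
#' @param x a [FitResult-class].
#' @return a [LifetimeParams-class] of length 1.
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
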