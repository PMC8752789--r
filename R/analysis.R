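# Application-level analyses: lifetime-barcode classification, FRET
# efficiency and glucose response, FLIRR metabolic mapping, and
# intensity-threshold segmentation.

#' Least-squares Gaussian fit of a lifetime histogram
#'
#' Bins the per-pixel lifetimes (default 0.05 ns bins) and fits
#' `A exp(-(x - mu)^2 / (2 sigma^2))` by nonlinear least squares;
#' the fitted `mu` is the representative lifetime of the region.
#' Falls back to `converged = FALSE` (with moment estimates) when the
#' fit degenerates.
#'
#' @param values numeric lifetimes (ns), at least 10.
#' @param bin_width histogram bin width in ns (default 0.05).
#' @return list with `mean`, `sd`, `converged`.
#' @export
fitGaussianHistogram <- function(values, bin_width = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 10)
    stop("at least 10 lifetime values are required for a Gaussian fit")
  br <- seq(floor(min(values) / bin_width) * bin_width,
            ceiling(max(values) / bin_width) * bin_width + bin_width,
            by = bin_width)
  hh <- graphics::hist(values, breaks = br, plot = FALSE)
  x <- hh$mids; y <- hh$counts
  m0 <- mean(values); s0 <- max(stats::sd(values), bin_width / 2)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sg^2)),
                        start = list(A = max(y), mu = m0, sg = s0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(stats::coef(fit)[["mu"]]))
    return(list(mean = m0, sd = s0, converged = FALSE))
  co <- stats::coef(fit)
  list(mean = unname(co[["mu"]]), sd = abs(unname(co[["sg"]])),
       converged = TRUE)
}

#' Midpoint cutoffs between sorted barcode class means
#'
#' @param class_means numeric vector of at least 2 distinct class mean
#'   lifetimes (ns).
#' @return strictly increasing cutoffs, each the midpoint of adjacent
#'   sorted class means.
#' @examples
#' barcodeCutoffs(c(1.90, 2.40, 3.50))  # 2.15, 2.95
#' @export
barcodeCutoffs <- function(class_means) {
  if (length(class_means) < 2)
    stop("at least two class means are required")
  m <- sort(class_means)
  cuts <- (m[-length(m)] + m[-1]) / 2
  if (any(diff(m) <= 0) || any(cuts <= m[-length(m)]) ||
      any(cuts >= m[-1]))
    stop("class means must be strictly distinct for midpoint cutoffs")
  cuts
}

#' Classify lifetime-barcode regions of interest
#'
#' Each ROI's per-pixel apparent lifetimes are histogram-binned and
#' Gaussian-fitted to a representative mean lifetime; ROIs are assigned
#' to the barcode class whose midpoint-cutoff interval contains that
#' mean. ROIs whose Gaussian fit degenerates are flagged unclassified.
#'
#' @param roi_lifetimes list of numeric vectors (>= 10 lifetimes each).
#' @param class_means numeric class mean lifetimes (>= 2, distinct).
#' @param bin_width Gaussian-fit histogram bin width (ns).
#' @return list with `class_means` (sorted), `cutoffs`, `roi_mean`,
#'   `assignment` (integer class index into the sorted means, NA when
#'   unclassified), and `unclassified` (logical).
#' @export
classifyBarcodes <- function(roi_lifetimes, class_means,
                             bin_width = 0.05) {
  cuts <- barcodeCutoffs(class_means)
  m <- sort(class_means)
  fits <- lapply(roi_lifetimes, function(v)
    tryCatch(fitGaussianHistogram(v, bin_width),
             error = function(e) list(mean = NA_real_, sd = NA_real_,
                                      converged = FALSE)))
  roi_mean <- vapply(fits, `[[`, numeric(1), "mean")
  ok <- vapply(fits, `[[`, logical(1), "converged")
  assignment <- ifelse(ok, findInterval(roi_mean, cuts) + 1L, NA_integer_)
  list(class_means = m, cutoffs = cuts, roi_mean = roi_mean,
       assignment = as.integer(assignment), unclassified = !ok)
}

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_DA / tau_D`, the fraction of donor excitations
#' transferred to the acceptor. Negative values are permitted (no
#' transfer within noise).
#'
#' @param tau_d donor-alone lifetime (ns, > 0).
#' @param tau_da donor lifetime in presence of the acceptor (ns).
#' @return efficiency (fraction < 1).
#' @examples
#' fretEfficiency(2.50, 2.30)  # 0.08
#' @export
fretEfficiency <- function(tau_d, tau_da) {
  if (any(!is.finite(tau_d)) || any(tau_d <= 0))
    stop("tau_d must be positive")
  1 - tau_da / tau_d
}

#' FRET efficiency from donor intensities
#'
#' `E = 1 - F_DA / F_D`; agrees with the lifetime form for ideal
#' photophysics, but is susceptible to photobleaching artifacts.
#'
#' @param f_d donor-alone intensity (> 0).
#' @param f_da donor intensity with acceptor.
#' @return efficiency (fraction < 1).
#' @export
fretEfficiencyIntensity <- function(f_d, f_da) {
  if (any(!is.finite(f_d)) || any(f_d <= 0))
    stop("f_d must be positive")
  1 - f_da / f_d
}

#' Sigmoidal (4-parameter logistic) fit of a FRET response curve
#'
#' Fits `E(c) = floor + (ceiling - floor) / (1 + exp(-slope (c - mid)))`
#' to efficiency-versus-concentration data by least squares and reports
#' the coefficient of determination.
#'
#' @param conc concentrations (mM), at least 4 points.
#' @param eff FRET efficiencies at those concentrations.
#' @return list with `floor`, `ceiling`, `mid`, `slope`, `r_squared`,
#'   `fitted`, `converged`.
#' @export
fitGlucoseResponse <- function(conc, eff) {
  if (length(conc) < 4 || length(conc) != length(eff))
    stop("at least 4 matched (conc, eff) points are required")
  rng <- range(eff)
  span <- max(diff(rng), 1e-8)
  cspan <- diff(range(conc))
  st <- list(lo = rng[1], hi = rng[2],
             mid = stats::median(conc),
             k = 1 / max(cspan / 4, 1e-3))
  # loose box constraints keep the weakly identified asymptotes from
  # running away under noise
  fit <- tryCatch(
    minpack.lm::nlsLM(eff ~ lo + (hi - lo) / (1 + exp(-k * (conc - mid))),
                      start = st,
                      lower = c(lo = rng[1] - span, hi = rng[1] - span,
                                mid = min(conc) - cspan, k = -1e3),
                      upper = c(lo = rng[2] + span, hi = rng[2] + span,
                                mid = max(conc) + cspan, k = 1e3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    sstot0 <- sum((eff - mean(eff))^2)
    return(list(floor = rng[1], ceiling = rng[2], mid = st$mid,
                slope = 0,
                r_squared = if (sstot0 == 0) 0 else NA_real_,
                fitted = rep(mean(eff), length(eff)), converged = FALSE))
  }
  co <- as.list(stats::coef(fit))
  fv <- stats::fitted(fit)
  sstot <- sum((eff - mean(eff))^2)
  # constant data: the sigmoid explains nothing beyond the mean
  r2 <- if (sstot > 0) 1 - sum((eff - fv)^2) / sstot else 0
  list(floor = co$lo, ceiling = co$hi, mid = co$mid, slope = co$k,
       r_squared = r2, fitted = as.numeric(fv), converged = TRUE)
}

#' Intensity-threshold segmentation of a cell image
#'
#' Pixels at or above `threshold` inside the cell are labeled
#' mitochondria, the remaining cell pixels cytoplasm, `nuclei_mask`
#' pixels nuclei, and pixels outside the cell background.
#'
#' @param intensity numeric intensity image (matrix).
#' @param threshold mitochondrial intensity threshold.
#' @param nuclei_mask optional logical matrix of (manually zeroed)
#'   nuclear pixels.
#' @param cell_mask optional logical matrix of cell pixels (default:
#'   intensity > 0).
#' @return character matrix with labels "background", "cytoplasm",
#'   "mitochondria", "nuclei". Warns (not errors) when the
#'   mitochondrial class is empty.
#' @export
segmentByIntensity <- function(intensity, threshold, nuclei_mask = NULL,
                               cell_mask = NULL) {
  if (is.null(cell_mask)) cell_mask <- intensity > 0
  labels <- matrix("background", nrow(intensity), ncol(intensity))
  labels[cell_mask] <- "cytoplasm"
  labels[cell_mask & intensity >= threshold] <- "mitochondria"
  if (!is.null(nuclei_mask)) labels[nuclei_mask] <- "nuclei"
  if (!any(labels == "mitochondria"))
    warning("empty mitochondrial class: threshold above all intensities")
  labels
}

#' FLIRR metabolic map and per-region histograms
#'
#' Fluorescence lifetime redox ratio per pixel:
#' `FLIRR = alpha2_NAD(P)H / alpha1_FAD`, the bound-fraction amplitude
#' of NAD(P)H over the short-lifetime amplitude of FAD. Pixels with
#' `alpha1_FAD = 0` (or labeled nuclei/background) are masked.
#'
#' @param alpha2_nadph matrix of NAD(P)H long-component (bound)
#'   amplitude fractions.
#' @param alpha1_fad matrix of FAD short-component amplitude fractions.
#' @param segmentation optional label matrix from
#'   [segmentByIntensity()]; enables per-region values.
#' @return list with `flirr` (matrix, NA where undefined), `mask`
#'   (logical, TRUE where masked), and `regions` (named list of FLIRR
#'   values for "mitochondria" and "cell_no_nuclei" when a segmentation
#'   is given).
#' @export
flirrMap <- function(alpha2_nadph, alpha1_fad, segmentation = NULL) {
  if (!all(dim(alpha2_nadph) == dim(alpha1_fad)))
    stop("co-registered maps of equal shape are required")
  mask <- !is.finite(alpha1_fad) | alpha1_fad <= 0 |
    !is.finite(alpha2_nadph)
  flirr <- alpha2_nadph / alpha1_fad
  flirr[mask] <- NA_real_
  regions <- NULL
  if (!is.null(segmentation)) {
    if (!all(dim(segmentation) == dim(flirr)))
      stop("segmentation shape mismatch")
    mask <- mask | segmentation %in% c("nuclei", "background")
    flirr[segmentation %in% c("nuclei", "background")] <- NA_real_
    regions <- list(
      mitochondria = flirr[segmentation == "mitochondria" & !mask],
      cell_no_nuclei = flirr[segmentation %in%
                               c("mitochondria", "cytoplasm") & !mask])
  }
  list(flirr = flirr, mask = mask, regions = regions)
}
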