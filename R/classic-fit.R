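# Classical per-pixel estimators: time-domain weighted least squares
# (TD_LSE), time-domain maximum likelihood (TD_MLE), and multi-harmonic
# phasor least squares (DFD_LSE).

.engineCache <- new.env(parent = emptyenv())

#' Fingerprint of an instrument response function
#'
#' Hash of the per-bin weights and grid, used to key cached fitting
#' tables and to guard trained network bundles against IRF changes.
#'
#' @param irf an [InstrumentResponse-class].
#' @return a character hash.
#' @export
irfFingerprint <- function(irf) {
  rlang::hash(list(round(irf@weights, 12), nBins(irf), period(irf)))
}

# Component-pmf lookup engine. decayPmf is linear in the mixture:
#   pmf(a, t1, t2) = (a s1 p1 + (1-a) s2 p2) / (a s1 + (1-a) s2),
# with p(tau) the area-normalized single-exponential pmf and
# s(tau) = tau (1 - exp(-T/tau)) its amplitude-true mass. Tabulating
# p(tau) once per IRF makes per-pixel fitting orders of magnitude
# cheaper than recomputing convolutions, at negligible accuracy cost
# (tau interpolated linearly on a 0.01 ns grid).
.pmfEngine <- function(irf, tau_min = 0.05, tau_max = 12,
                       tau_step = 0.01) {
  key <- rlang::hash(list(irfFingerprint(irf), tau_min, tau_max, tau_step))
  hit <- .engineCache[[key]]
  if (!is.null(hit)) return(hit)
  nb <- nBins(irf)
  os <- if (irf@oversample %% 16L == 0L) 16L else irf@oversample
  fine <- if (os == irf@oversample) irf@fine_weights else
    colSums(matrix(irf@fine_weights, nrow = irf@oversample %/% os))
  M <- nb * os
  ws <- period(irf) / M
  taus <- seq(tau_min, tau_max, by = tau_step)
  irf_fft <- stats::fft(fine)
  P <- matrix(0, length(taus), nb)
  for (i in seq_along(taus)) {
    cv <- pmax(.circConv(.expMasses(taus[i], M, ws), irf_fft), 0)
    p <- colSums(matrix(cv, nrow = os))
    P[i, ] <- p / sum(p)
  }
  Tt <- period(irf)
  Pt <- t(P)   # column access is contiguous
  ntau <- length(taus)
  comp <- function(tau) {
    tau <- min(max(tau, tau_min), tau_max)
    x <- (tau - tau_min) / tau_step
    i0 <- min(floor(x), ntau - 2)
    f <- x - i0
    (1 - f) * Pt[, i0 + 1] + f * Pt[, i0 + 2]
  }
  eng <- list(
    comp = comp,
    sigma = function(tau) tau * (1 - exp(-Tt / tau)),
    pmf = function(a, t1, t2) {
      s1 <- t1 * (1 - exp(-Tt / t1)); s2 <- t2 * (1 - exp(-Tt / t2))
      w1 <- a * s1; w2 <- (1 - a) * s2
      (w1 * comp(t1) + w2 * comp(t2)) / (w1 + w2)
    },
    tau_min = tau_min, tau_max = tau_max)
  .engineCache[[key]] <- eng
  eng
}

# Phasor-guided multi-start initial values for (alpha1, tau1, tau2).
.initGrid <- function(h, irf) {
  tp <- tryCatch({
    p <- irfCorrectPhasor(decayPhasor(h, 1L), decayPhasor(irf, 1L))
    max(min(tauPhase(p), 8), 0.3)
  }, error = function(e) 2.5)
  list(c(0.5, 0.6 * tp, 1.5 * tp),
       c(0.3, 0.3 * tp, 1.2 * tp),
       c(0.7, 0.8 * tp, 2.5 * tp),
       c(0.5, 1.0, 3.0))
}

# Shared minimizer: Nelder-Mead over (logit alpha, log tau1, log tau2)
# for model order 2, or 1-d search over log tau for order 1.
.fitDecay <- function(h, irf, objective_fn, model_order, tau_ceiling,
                      align, reference_offset, method_label) {
  cnt <- counts(h)
  if (sum(cnt) == 0) stop("all-zero histogram: nothing to fit")
  grid <- decayGrid(h)
  eng <- .pmfEngine(irf)
  ref <- if (align)
    (circularCoM(irf@weights, grid) + reference_offset) %% period(grid)
    else NA_real_
  modelPmf <- function(a, t1, t2) {
    p <- eng$pmf(a, t1, t2)
    if (align) p <- .alignPmf(p, grid, ref)
    p
  }
  evals <- 0L
  obj3 <- function(theta) {
    evals <<- evals + 1L
    a <- stats::plogis(theta[1])
    t1 <- exp(theta[2]); t2 <- exp(theta[3])
    if (!is.finite(t1) || !is.finite(t2)) return(1e18)
    t1 <- min(max(t1, eng$tau_min), eng$tau_max)
    t2 <- min(max(t2, eng$tau_min), eng$tau_max)
    objective_fn(modelPmf(a, t1, t2))
  }
  if (model_order == 2L) {
    starts <- .initGrid(h, irf)
    # a coarse objective scan contributes one extra start: the
    # two-component likelihood has flat alpha/tau trade-off ridges
    # that strand purely local searches
    tp <- starts[[1]][3] / 1.5
    scan <- expand.grid(a = c(0.15, 0.5, 0.85),
                        t1 = tp * c(0.2, 0.5, 0.9),
                        t2 = tp * c(1.1, 1.8, 3.0))
    sv <- vapply(seq_len(nrow(scan)), function(i)
      obj3(c(stats::qlogis(scan$a[i]), log(scan$t1[i]),
             log(scan$t2[i]))), numeric(1))
    bi <- which.min(sv)
    starts[[length(starts) + 1L]] <- as.numeric(scan[bi, ])
    best <- NULL
    for (st in starts) {
      th0 <- c(stats::qlogis(st[1]), log(st[2]), log(st[3]))
      o <- stats::optim(th0, obj3, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-8))
      if (is.null(best) || o$value < best$value) best <- o
    }
    # restart once from the incumbent with a fresh simplex
    o <- stats::optim(best$par, obj3, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
    if (o$value < best$value) best <- o
    a <- stats::plogis(best$par[1])
    t1 <- min(max(exp(best$par[2]), eng$tau_min), eng$tau_max)
    t2 <- min(max(exp(best$par[3]), eng$tau_min), eng$tau_max)
    conv <- best$convergence == 0L
    val <- best$value
  } else {
    obj1 <- function(lt) {
      evals <<- evals + 1L
      t1 <- min(max(exp(lt), eng$tau_min), eng$tau_max)
      objective_fn(modelPmf(1, t1, t1))
    }
    o <- stats::optimize(obj1, interval = log(c(eng$tau_min, eng$tau_max)),
                         tol = 1e-9)
    a <- 1
    t1 <- t2 <- min(max(exp(o$minimum), eng$tau_min), eng$tau_max)
    conv <- TRUE
    val <- o$objective
  }
  failed <- FALSE
  if (is.finite(tau_ceiling)) {
    if (t1 >= tau_ceiling) t1 <- tau_ceiling
    if (t2 >= tau_ceiling) t2 <- tau_ceiling
    p_tmp <- lifetimeParams(a, t1, t2)
    failed <- apparentLifetime(p_tmp) >= tau_ceiling - 1e-9
  }
  new("FitResult", params = lifetimeParams(a, t1, t2),
      objective = as.numeric(val), method = method_label,
      converged = isTRUE(conv) && is.finite(val),
      n_iter = evals, failed = failed)
}

#' Time-domain weighted least-squares lifetime fit (TD_LSE)
#'
#' Minimizes the Neyman chi-square
#' `sum_k w_k (counts_k - N pmf_k(theta))^2` with weights
#' `w_k = 1/max(counts_k, 1)` (set `weighting = "none"` for an
#' unweighted fit), over a 4-point multi-start simplex search.
#' Least-squares fitting of Poisson-distributed counts is biased at low
#' photon budgets; this estimator is provided as the commercial-practice
#' baseline.
#'
#' @param h a [DecayHistogram-class] with at least one photon.
#' @param irf the [InstrumentResponse-class].
#' @param model_order 1 (mono-exponential) or 2 (bi-exponential).
#' @param weighting `"neyman"` (default) or `"none"`.
#' @param tau_ceiling lifetime ceiling in ns (default 6); estimates at
#'   the ceiling are clamped and flagged as failed pixels.
#' @param align fit in CoME-canonicalized space (model pmfs are aligned
#'   with the same convention as [comeAlign()]); use after aligning `h`.
#' @param reference_offset alignment reference offset in ns.
#' @return a [FitResult-class] with canonical parameter order.
#' @export
fitTDLSE <- function(h, irf, model_order = 2L,
                     weighting = c("neyman", "none"), tau_ceiling = 6,
                     align = FALSE, reference_offset = 0) {
  weighting <- match.arg(weighting)
  cnt <- counts(h)
  N <- sum(cnt)
  w <- if (weighting == "neyman") 1 / pmax(cnt, 1) else rep(1, length(cnt))
  fn <- function(pmf) sum(w * (cnt - N * pmf)^2)
  .fitDecay(h, irf, fn, as.integer(model_order), tau_ceiling, align,
            reference_offset, "td_lse")
}

#' Time-domain maximum-likelihood lifetime fit (TD_MLE)
#'
#' Maximizes the multinomial log-likelihood
#' `sum_k counts_k log pmf_k(theta)` (reported objective is the negative
#' log-likelihood). The statistically efficient gold-standard estimator
#' for Poisson photon-counting data.
#'
#' @inheritParams fitTDLSE
#' @return a [FitResult-class].
#' @export
fitTDMLE <- function(h, irf, model_order = 2L, tau_ceiling = 6,
                     align = FALSE, reference_offset = 0) {
  cnt <- counts(h)
  nz <- which(cnt > 0L)
  cnz <- cnt[nz]
  fn <- function(pmf) -sum(cnz * log(pmax(pmf[nz], 1e-300)))
  .fitDecay(h, irf, fn, as.integer(model_order), tau_ceiling, align,
            reference_offset, "td_mle")
}

#' Phasor (Fourier) coordinates of a decay at a harmonic
#'
#' `g = sum_k c_k cos(n w t_k) / N`, `s = sum_k c_k sin(n w t_k) / N`
#' at bin centers, with `w = 2 pi / period`.
#'
#' @param h a [DecayHistogram-class] or [InstrumentResponse-class].
#' @param harmonic positive integer harmonic number.
#' @return a [PhasorPoint-class].
#' @export
decayPhasor <- function(h, harmonic = 1L) {
  if (is(h, "InstrumentResponse")) {
    x <- irfWeights(h); grid <- decayGrid(h)
  } else {
    x <- counts(h); grid <- decayGrid(h)
  }
  tot <- sum(x)
  if (tot <= 0) stop("total = 0: phasor undefined")
  n <- as.integer(harmonic)
  om <- n * 2 * pi / period(grid)
  tc <- binCenters(grid)
  new("PhasorPoint", harmonic = n, omega = om,
      g = sum(x * cos(om * tc)) / tot,
      s = sum(x * sin(om * tc)) / tot)
}

#' Remove the IRF contribution from a phasor
#'
#' Complex division `(g + i s) / (g_irf + i s_irf)`: convolution with
#' the IRF multiplies Fourier coefficients, so dividing by the IRF
#' phasor recovers the pure-decay phasor. A delta IRF (phasor (1, 0))
#' leaves the input unchanged.
#'
#' @param p a [PhasorPoint-class] of the measured decay.
#' @param irf_phasor a [PhasorPoint-class] of the IRF at the same
#'   harmonic (must have nonzero modulation).
#' @return the corrected [PhasorPoint-class].
#' @export
irfCorrectPhasor <- function(p, irf_phasor) {
  if (p@harmonic != irf_phasor@harmonic)
    stop("phasors must be at the same harmonic")
  if (modulation(irf_phasor) <= 0)
    stop("zero IRF modulation: cannot correct")
  z <- complex(real = p@g, imaginary = p@s) /
    complex(real = irf_phasor@g, imaginary = irf_phasor@s)
  new("PhasorPoint", harmonic = p@harmonic, omega = p@omega,
      g = Re(z), s = Im(z))
}

#' Mono-exponential lifetime from phasor phase
#' @param p an IRF-corrected [PhasorPoint-class].
#' @return `tan(phi)/omega` in ns.
#' @export
tauPhase <- function(p) tan(phase(p)) / p@omega

#' Mono-exponential lifetime from phasor modulation
#' @param p an IRF-corrected [PhasorPoint-class].
#' @return `sqrt(1/m^2 - 1)/omega` in ns.
#' @export
tauMod <- function(p) {
  m <- modulation(p)
  sqrt(max(1 / m^2 - 1, 0)) / p@omega
}

# Analytic phasor of a periodic multi-exponential decay: intensity-
# weighted combination of 1/(1 - i omega tau).
.modelPhasor <- function(a, t1, t2, omega) {
  w1 <- a * t1; w2 <- (1 - a) * t2
  z <- (w1 / (1 - 1i * omega * t1) + w2 / (1 - 1i * omega * t2)) / (w1 + w2)
  z
}

#' Multi-harmonic phasor least-squares lifetime fit (DFD_LSE)
#'
#' Computes IRF-corrected phasors at the requested harmonics and fits
#' the analytic one- or two-component phasor model jointly to the
#' stacked modulation and phase residuals by least squares. Estimates
#' reaching the lifetime ceiling (default 6 ns) are clamped and flagged
#' as failed pixels.
#'
#' @inheritParams fitTDLSE
#' @param harmonics integer vector of harmonic numbers (default 1:5).
#'   Model order 1 requires at least one, order 2 at least two.
#' @return a [FitResult-class].
#' @export
fitDFDLSE <- function(h, irf, harmonics = 1:5, model_order = 2L,
                      tau_ceiling = 6) {
  model_order <- as.integer(model_order)
  if (model_order == 2L && length(harmonics) < 2L)
    stop("model order 2 requires at least two harmonics")
  if (length(harmonics) < 1L)
    stop("at least one harmonic is required")
  cnt <- counts(h)
  if (sum(cnt) == 0) stop("all-zero histogram: nothing to fit")
  grid <- decayGrid(h)
  corr <- lapply(harmonics, function(n)
    irfCorrectPhasor(decayPhasor(h, n), decayPhasor(irf, n)))
  m_obs <- vapply(corr, modulation, numeric(1))
  ph_obs <- vapply(corr, phase, numeric(1))
  omegas <- vapply(corr, function(p) p@omega, numeric(1))
  evals <- 0L
  resid <- function(a, t1, t2) {
    z <- .modelPhasor(a, t1, t2, omegas)
    dphi <- (ph_obs - Arg(z) + pi) %% (2 * pi) - pi
    c(m_obs - Mod(z), dphi)
  }
  tmin <- 0.01; tmax <- 12
  if (model_order == 2L) {
    obj <- function(theta) {
      evals <<- evals + 1L
      a <- stats::plogis(theta[1])
      t1 <- min(max(exp(theta[2]), tmin), tmax)
      t2 <- min(max(exp(theta[3]), tmin), tmax)
      sum(resid(a, t1, t2)^2)
    }
    best <- NULL
    for (st in .initGrid(h, irf)) {
      th0 <- c(stats::qlogis(st[1]), log(st[2]), log(st[3]))
      o <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
      if (is.null(best) || o$value < best$value) best <- o
    }
    a <- stats::plogis(best$par[1])
    t1 <- min(max(exp(best$par[2]), tmin), tmax)
    t2 <- min(max(exp(best$par[3]), tmin), tmax)
    conv <- best$convergence == 0L
    val <- best$value
  } else {
    obj <- function(lt) {
      evals <<- evals + 1L
      t1 <- min(max(exp(lt), tmin), tmax)
      sum(resid(1, t1, t1)^2)
    }
    o <- stats::optimize(obj, interval = log(c(tmin, tmax)), tol = 1e-10)
    a <- 1
    t1 <- t2 <- min(max(exp(o$minimum), tmin), tmax)
    conv <- TRUE
    val <- o$objective
  }
  failed <- FALSE
  if (is.finite(tau_ceiling)) {
    if (t1 >= tau_ceiling) t1 <- tau_ceiling
    if (t2 >= tau_ceiling) t2 <- tau_ceiling
    failed <- apparentLifetime(lifetimeParams(a, t1, t2)) >=
      tau_ceiling - 1e-9
  }
  new("FitResult", params = lifetimeParams(a, t1, t2),
      objective = as.numeric(val), method = "dfd_lse",
      converged = isTRUE(conv) && is.finite(val),
      n_iter = evals, failed = failed)
}

#' Fit every pixel of a decay cube with a classical estimator
#'
#' @param cube a [DecayCube-class].
#' @param irf the [InstrumentResponse-class].
#' @param method one of "td_mle", "td_lse", "dfd_lse".
#' @param min_photons pixels with fewer photons are marked failed and
#'   receive NA estimates.
#' @param ... passed to the per-pixel fitter.
#' @return a list of H x W matrices: `tau_apparent`, `alpha1`, `tau1`,
#'   `tau2`, and logical `failed`.
#' @export
fitCube <- function(cube, irf, method = c("td_mle", "td_lse", "dfd_lse"),
                    min_photons = 1L, ...) {
  method <- match.arg(method)
  fitter <- switch(method, td_mle = fitTDMLE, td_lse = fitTDLSE,
                   dfd_lse = fitDFDLSE)
  d <- dim(cube)
  out <- list(tau_apparent = matrix(NA_real_, d[1], d[2]),
              alpha1 = matrix(NA_real_, d[1], d[2]),
              tau1 = matrix(NA_real_, d[1], d[2]),
              tau2 = matrix(NA_real_, d[1], d[2]),
              failed = matrix(TRUE, d[1], d[2]))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    h <- cubePixel(cube, i, j)
    if (totalCounts(h) < min_photons) next
    fr <- fitter(h, irf, ...)
    p <- fitParams(fr)
    out$tau_apparent[i, j] <- apparentLifetime(p)
    out$alpha1[i, j] <- alpha1(p)
    out$tau1[i, j] <- tau1(p)
    out$tau2[i, j] <- tau2(p)
    out$failed[i, j] <- fr@failed
  }
  out
}
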