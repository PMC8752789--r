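test_that("TD_LSE recovers its own forward model on noiseless data", {
  p <- decayPmf(lifetimeParams(1, 2, 2), fk_irf)
  h <- decayHistogram(round(1e6 * p), fk_grid)
  fit <- fitTDLSE(h, fk_irf, model_order = 1L)
  expect_true(fit@converged)
  expect_lt(abs(tau1(fitParams(fit)) - 2.0), 0.02)
})

test_that("TD_MLE is calibrated on mono-exponential truth at high
          counts", {
  p <- decayPmf(lifetimeParams(1, 3, 3), fk_irf)
  set.seed(21)
  est <- replicate(200, {
    h <- sampleDecay(p, 1500, fk_grid)
    tau1(fitParams(fitTDMLE(h, fk_irf, model_order = 1L)))
  })
  expect_lt(abs(mean(est) - 3.0), 0.05)
})

test_that("MLE bias shrinks as the photon budget grows", {
  p <- decayPmf(lifetimeParams(1, 2.2, 2.2), fk_irf)
  set.seed(22)
  est_lo <- replicate(120, tau1(fitParams(fitTDMLE(
    sampleDecay(p, 150, fk_grid), fk_irf, model_order = 1L))))
  est_hi <- replicate(120, tau1(fitParams(fitTDMLE(
    sampleDecay(p, 1500, fk_grid), fk_irf, model_order = 1L))))
  expect_lt(abs(mean(est_hi) - 2.2), abs(mean(est_lo) - 2.2) + 0.02)
  expect_lt(abs(mean(est_hi) - 2.2), 0.03)
})

test_that("MLE optimum beats a brute-force likelihood lattice", {
  # lattice over (alpha1, tau1) with tau2 held at truth; mixture pmfs
  # assembled from single-component pmfs via convolution linearity
  a_grid <- seq(0.05, 0.95, length.out = 50)
  t1_grid <- seq(0.3, 2.4, length.out = 50)
  sig <- function(tau) tau * (1 - exp(-50 / tau))
  comp1 <- decayPmf(lifetimeParams(rep(1, 50), t1_grid, t1_grid), fk_irf)
  set.seed(23)
  for (i in 1:10) {
    a <- runif(1, 0.2, 0.8); t1 <- runif(1, 0.5, 2); t2 <- runif(1, 2.5, 5)
    p <- decayPmf(lifetimeParams(a, t1, t2), fk_irf)
    h <- sampleDecay(p, 300, fk_grid)
    fit <- fitTDMLE(h, fk_irf, tau_ceiling = Inf)
    cnt <- counts(h); nz <- which(cnt > 0)
    comp2 <- decayPmf(lifetimeParams(1, t2, t2), fk_irf)
    lat_min <- Inf
    for (j in seq_along(t1_grid)) {
      w1 <- a_grid * sig(t1_grid[j]); w2 <- (1 - a_grid) * sig(t2)
      pm <- (outer(w1, comp1[j, nz]) + outer(w2, comp2[nz])) / (w1 + w2)
      lat_min <- min(lat_min,
                     min(-as.vector(log(pmax(pm, 1e-300)) %*% cnt[nz])))
    }
    p_hat <- decayPmf(fitParams(fit), fk_irf)
    nll_hat <- -sum(cnt[nz] * log(pmax(p_hat[nz], 1e-300)))
    expect_lte(nll_hat, lat_min + 0.01)
  }
})

test_that("decay phasor obeys its closed forms", {
  g4 <- fk_grid
  # all counts in the first bin: (g, s) ~ (1, 0) up to the bin-center
  # phase
  cnt <- integer(256); cnt[1] <- 1000L
  ph <- decayPhasor(decayHistogram(cnt, g4), 1L)
  expect_equal(phase(ph), 2 * pi * binCenters(g4)[1] / 50,
               tolerance = 1e-9)
  expect_equal(modulation(ph), 1, tolerance = 1e-12)
  # mono-exponential with omega * tau = 1 sits at (0.5, 0.5)
  tau <- 50 / (2 * pi)
  p <- decayPmf(lifetimeParams(1, tau, tau), deltaIRF(g4, onset = 0))
  h <- decayHistogram(round(p * 1e7), g4)
  ph2 <- decayPhasor(h, 1L)
  expect_lt(abs(ph2@g - 0.5), 1e-3)
  expect_lt(abs(ph2@s - 0.5), 1e-3)
  # uniform counts have no modulation
  ph3 <- decayPhasor(decayHistogram(rep(5L, 256), g4), 1L)
  expect_lt(abs(ph3@g), 1e-12)
  expect_lt(abs(ph3@s), 1e-12)
  expect_error(decayPhasor(decayHistogram(integer(256), g4)), "total")
})

test_that("IRF phasor correction is an exact complex division", {
  p <- decayPhasor(decayHistogram(as.integer(round(1e6 *
    decayPmf(lifetimeParams(1, 2, 2), fk_irf))), fk_grid), 1L)
  irf_p <- decayPhasor(fk_irf, 1L)
  # self-division lands on (1, 0)
  self <- irfCorrectPhasor(p, p)
  expect_equal(c(self@g, self@s), c(1, 0), tolerance = 1e-12)
  # delta IRF leaves the phasor unchanged
  delta_p <- new("PhasorPoint", harmonic = 1L, omega = p@omega,
                 g = 1, s = 0)
  same <- irfCorrectPhasor(p, delta_p)
  expect_equal(c(same@g, same@s), c(p@g, p@s))
  expect_error(irfCorrectPhasor(p, new("PhasorPoint", harmonic = 1L,
                                       omega = p@omega, g = 0, s = 0)),
               "modulation")
  expect_s4_class(irfCorrectPhasor(p, irf_p), "PhasorPoint")
})

test_that("IRF-corrected mono-exponential phasors sit on the universal
          semicircle", {
  p <- decayPmf(lifetimeParams(1, 2.5, 2.5), fk_irf)
  set.seed(24)
  r <- replicate(30, {
    h <- sampleDecay(p, 1000, fk_grid)
    cp <- irfCorrectPhasor(decayPhasor(h, 1L), decayPhasor(fk_irf, 1L))
    sqrt((cp@g - 0.5)^2 + cp@s^2)
  })
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 0.5), 3 * se + 1e-3)
})

test_that("two-component phasor is the intensity-weighted combination of
          its components (noiseless)", {
  a <- 0.4; t1 <- 1; t2 <- 4
  irf0 <- deltaIRF(fk_grid, onset = 0)
  mix <- decayPhasor(decayHistogram(round(1e7 *
    decayPmf(lifetimeParams(a, t1, t2), irf0)), fk_grid), 2L)
  p1 <- decayPhasor(decayHistogram(round(1e7 *
    decayPmf(lifetimeParams(1, t1, t1), irf0)), fk_grid), 2L)
  p2 <- decayPhasor(decayHistogram(round(1e7 *
    decayPmf(lifetimeParams(1, t2, t2), irf0)), fk_grid), 2L)
  f1 <- a * t1 / (a * t1 + (1 - a) * t2)
  expect_equal(mix@g, f1 * p1@g + (1 - f1) * p2@g, tolerance = 1e-4)
  expect_equal(mix@s, f1 * p1@s + (1 - f1) * p2@s, tolerance = 1e-4)
})

test_that("phase and modulation lifetimes invert a noiseless
          mono-exponential", {
  p <- decayPmf(lifetimeParams(1, 2.5, 2.5), fk_irf)
  h <- decayHistogram(round(1e7 * p), fk_grid)
  cp <- irfCorrectPhasor(decayPhasor(h, 1L), decayPhasor(fk_irf, 1L))
  expect_lt(abs(tauPhase(cp) - 2.5), 0.01)
  expect_lt(abs(tauMod(cp) - 2.5), 0.01)
  fit <- fitDFDLSE(h, fk_irf, harmonics = 1L, model_order = 1L)
  expect_lt(abs(tau1(fitParams(fit)) - 2.5), 0.01)
})

test_that("DFD_LSE guards harmonics and flags ceiling-clamped pixels", {
  h <- decayHistogram(round(1e6 *
    decayPmf(lifetimeParams(1, 8, 8), fk_irf)), fk_grid)
  expect_error(fitDFDLSE(h, fk_irf, harmonics = 1L, model_order = 2L),
               "two harmonics")
  expect_error(fitDFDLSE(h, fk_irf, harmonics = integer(0),
                         model_order = 1L), "harmonic")
  fit <- fitDFDLSE(h, fk_irf, harmonics = 1:3, model_order = 1L)
  expect_true(fit@failed)
  expect_equal(tau1(fitParams(fit)), 6)
})

test_that("cube fitting returns per-pixel maps with failure flags", {
  pat <- list(alpha1 = matrix(1, 2, 3), tau1 = matrix(2, 2, 3),
              tau2 = matrix(2, 2, 3))
  cube <- simulateBenchmarkImage(pat, rate = 800, irf = fk_irf, seed = 6)
  maps <- fitCube(cube, fk_irf, method = "td_mle", model_order = 1L)
  expect_equal(dim(maps$tau_apparent), c(2L, 3L))
  expect_true(all(is.finite(maps$tau_apparent)))
  expect_true(all(abs(maps$tau_apparent - 2) < 0.5))
  expect_false(any(maps$failed))
})
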