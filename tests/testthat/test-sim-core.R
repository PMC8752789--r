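test_that("histogram grid exposes a strictly increasing time axis", {
  g <- histogramGrid(256, 50)
  expect_equal(nBins(g), 256L)
  expect_equal(binWidth(g), 50 / 256)
  tc <- binCenters(g)
  expect_length(tc, 256)
  expect_true(all(diff(tc) > 0))
  expect_error(histogramGrid(1, 50))
  expect_error(histogramGrid(256, -1))
})

test_that("gaussian IRF is normalized with its mode at the onset bin", {
  irf <- gaussianIRF(fk_grid, fwhm = 0.5, onset = 5)
  w <- irfWeights(irf)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
  # onset 5 ns on a 0.1953 ns grid falls in bin 26 (1-based)
  expect_equal(which.max(w), floor(5 / binWidth(fk_grid)) + 1L)
  expect_error(gaussianIRF(fk_grid, fwhm = 20, onset = 5), "period/4")
  expect_error(gaussianIRF(fk_grid, fwhm = 0.5, onset = 60), "period")
})

test_that("zero-width IRF limit is a discrete delta at the onset", {
  irf <- deltaIRF(fk_grid, onset = 5)
  w <- irfWeights(irf)
  expect_equal(sum(w > 0), 1L)
  expect_equal(which.max(w), floor(5 / binWidth(fk_grid)) + 1L)
})

test_that("decay pmf is a probability vector", {
  set.seed(1)
  for (i in 1:5) {
    a <- runif(1); t1 <- runif(1, 0.2, 3); t2 <- runif(1, t1, 9)
    p <- decayPmf(lifetimeParams(a, t1, t2), fk_irf)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("pure exponential through a delta IRF decays geometrically", {
  p <- decayPmf(lifetimeParams(1, 2, 2), deltaIRF(fk_grid, onset = 0))
  ratio <- p[2:200] / p[1:199]
  expect_equal(ratio, rep(exp(-binWidth(fk_grid) / 2), 199),
               tolerance = 1e-5)
})

test_that("decay pmf matches the fine-grid convolution oracle", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1); t1 <- runif(1, 0.3, 4); t2 <- runif(1, t1, 8)
    p <- decayPmf(lifetimeParams(a, t1, t2), fk_irf)
    expect_lt(max(abs(p - fk_pmf_oracle(a, t1, t2))), 1e-4)
  }
  # the printed two-dye mixture point specifically
  p <- decayPmf(lifetimeParams(0.5, 0.6, 3.3), fk_irf)
  expect_lt(max(abs(p - fk_pmf_oracle(0.5, 0.6, 3.3))), 1e-4)
})

test_that("decay pmf rejects a mismatched output grid", {
  expect_error(decayPmf(lifetimeParams(1, 2, 2), fk_irf,
                        grid = histogramGrid(128, 50)),
               "grid mismatch")
})

test_that("alpha1 = 1 makes the pmf independent of tau2", {
  p1 <- decayPmf(lifetimeParams(1, 2, 5), fk_irf)
  p2 <- decayPmf(lifetimeParams(1, 2, 9), fk_irf)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("photon sampling conserves counts and honours the pmf", {
  p <- decayPmf(lifetimeParams(0.6, 1, 3), fk_irf)
  h <- sampleDecay(p, 200, fk_grid, seed = 5)
  expect_equal(totalCounts(h), sum(counts(h)))
  # delta pmf puts every photon in that bin
  pd <- rep(0, 256); pd[40] <- 1
  hd <- sampleDecay(pd, 100, fk_grid, seed = 6)
  expect_equal(sum(counts(hd)[-40]), 0L)
  expect_error(sampleDecay(p * 2, 100, fk_grid), "summing to 1")
  # fixed-total mode bypasses the Poisson draw
  hf <- sampleDecay(p, 100, fk_grid, seed = 7, total = 123L)
  expect_equal(totalCounts(hf), 123L)
})

test_that("sampled totals are Poisson with the requested rate", {
  p <- decayPmf(lifetimeParams(0.5, 1, 3), fk_irf)
  set.seed(8)
  totals <- replicate(1000, totalCounts(sampleDecay(p, 1500, fk_grid)))
  expect_lt(abs(mean(totals) - 1500), 4 * sqrt(1500 / 1000))
})

test_that("per-bin sample means match the analytic mean counts", {
  p <- decayPmf(lifetimeParams(1, 2.5, 2.5), fk_irf)
  set.seed(9)
  n_draw <- 4000
  acc <- numeric(256)
  for (i in seq_len(n_draw))
    acc <- acc + counts(sampleDecay(p, 100, fk_grid))
  m <- acc / n_draw
  se <- sqrt(100 * p * (1 + 100 * p / 100) / n_draw)  # Poisson bin sd
  keep <- p > 1e-4
  expect_true(all(abs(m - 100 * p)[keep] < 5 * pmax(se[keep], 1e-3)))
})

test_that("training library retains the expected grid and sizes", {
  # grids sized to retain exactly 600 combinations
  lib <- buildTrainingLibrary(fk_irf,
    alpha_grid = seq(0.1, 0.6, by = 0.1),
    tau1_grid = seq(0.5, 2.3, length.out = 10),
    tau2_grid = seq(2.5, 6.0, length.out = 10),
    rates = c(50, 1500), per_truth = 5L, thin_to = NULL, seed = 3L)
  expect_equal(nrow(lib@pmfs), 600L)
  expect_equal(nrow(lib@degraded), 3000L)
  expect_true(all(lib@parent %in% seq_len(600)))
  expect_equal(max(abs(rowSums(lib@pmfs) - 1)), 0, tolerance = 1e-8)
  expect_true(all(tau1(truthParams(lib)) <= tau2(truthParams(lib))))
})

test_that("full-scale library matches the published training set size", {
  lib <- buildTrainingLibrary(fk_irf,
    alpha_grid = seq(0.1, 0.6, by = 0.1),
    tau1_grid = seq(0.5, 2.3, length.out = 10),
    tau2_grid = seq(2.5, 6.0, length.out = 10),
    rates = c(50, 100, 150, 300, 600, 1500), per_truth = 500L,
    thin_to = NULL, seed = 4L)
  expect_equal(nrow(lib@pmfs), 600L)
  expect_equal(nrow(lib@degraded), 300000L)
  expect_equal(sum(rowSums(lib@degraded) == rowSums(lib@degraded)),
               300000L)
  rm(lib)
})

test_that("library generation is deterministic under a fixed seed", {
  a <- fk_small_lib(per_truth = 4L, seed = 7L)
  b <- fk_small_lib(per_truth = 4L, seed = 7L)
  expect_identical(a@degraded, b@degraded)
  expect_identical(a@pmfs, b@pmfs)
})

test_that("empty retained grid is rejected", {
  expect_error(buildTrainingLibrary(fk_irf, alpha_grid = 0.5,
                                    tau1_grid = 5, tau2_grid = 1,
                                    per_truth = 1L),
               "no parameter combinations")
})

test_that("benchmark image simulation attaches truth and degenerates to
          a single histogram for a 1x1 pattern", {
  pat <- list(alpha1 = matrix(0.5), tau1 = matrix(1.5),
              tau2 = matrix(3.5))
  cube <- simulateBenchmarkImage(pat, rate = 500, irf = fk_irf, seed = 2)
  expect_equal(dim(cube), c(1L, 1L))
  h <- cubePixel(cube, 1, 1)
  expect_s4_class(h, "DecayHistogram")
  expect_equal(totalCounts(cube)[1, 1], totalCounts(h))
  expect_equal(length(truthParams(cube)), 1L)
})

test_that("estimator error grows as the photon budget shrinks", {
  pat <- list(alpha1 = matrix(0.5, 4, 6), tau1 = matrix(1.2, 4, 6),
              tau2 = matrix(3.2, 4, 6))
  truth_ta <- 0.5 * 1.2 + 0.5 * 3.2
  mse_at <- function(rate, seeds) {
    vapply(seeds, function(s) {
      cube <- simulateBenchmarkImage(pat, rate = rate, irf = fk_irf,
                                     seed = s)
      maps <- fitCube(cube, fk_irf, method = "td_mle")
      mean((maps$tau_apparent - truth_ta)^2)
    }, numeric(1))
  }
  lo <- mse_at(50, 1:10)
  hi <- mse_at(1500, 1:10)
  expect_gt(mean(lo), mean(hi))
})

test_that("glyph pattern is deterministic with two parameter regions", {
  p1 <- glyphPattern()
  p2 <- glyphPattern()
  expect_identical(p1, p2)
  expect_equal(dim(p1$alpha1), c(14L, 47L))
  expect_true(any(p1$mask) && !all(p1$mask))
  expect_equal(length(unique(as.vector(p1$tau1))), 2L)
})

test_that("mixture amplitude fraction is symmetric and bounded", {
  expect_equal(mixtureAlpha(1, 1, 1, 1), 0.5)
  expect_equal(mixtureAlpha(3, 2, 7, 5),
               1 - mixtureAlpha(7, 5, 3, 2))
  expect_gt(mixtureAlpha(1, 1, 1e-9, 1), 0.999)
  expect_error(mixtureAlpha(1, 1, -1, 1), "positive")
})

test_that("apparent lifetime spans the printed two-dye interval", {
  # Cy5-NHS (0.60 ns) / Atto633 (3.30 ns) mixtures sweep 0.60-3.30 ns
  mix <- seq(0, 1, by = 0.1)
  ta <- apparentLifetime(lifetimeParams(mix, 0.60, 3.30))
  expect_equal(min(ta), 0.60)
  expect_equal(max(ta), 3.30)
  expect_true(all(diff(ta) < 0))   # monotone towards tau1 as alpha1 grows
})

test_that("apparent lifetime is bounded by its components", {
  set.seed(10)
  a <- runif(50); t1 <- runif(50, 0.1, 5); t2 <- runif(50, 0.1, 9)
  p <- lifetimeParams(a, t1, t2)
  ta <- apparentLifetime(p)
  expect_true(all(ta >= tau1(p) - 1e-12 & ta <= tau2(p) + 1e-12))
  expect_true(all(tau1(p) <= tau2(p)))
})
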