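test_that("apparent lifetime reproduces the printed mixture arithmetic", {
  expect_equal(apparentLifetime(lifetimeParams(1, 0.60, 3.30)), 0.60)
  expect_equal(apparentLifetime(lifetimeParams(0, 0.60, 3.30)), 3.30)
  expect_equal(apparentLifetime(lifetimeParams(0.5, 0.60, 3.30)), 1.95)
})

test_that("barcode cutoffs are the printed midpoints and degenerate
          means are rejected", {
  expect_equal(barcodeCutoffs(c(1.90, 2.40, 3.50)), c(2.15, 2.95))
  expect_equal(barcodeCutoffs(c(3.50, 1.90, 2.40)), c(2.15, 2.95))
  expect_error(barcodeCutoffs(c(2.4, 2.4, 3.5)), "distinct")
  expect_error(barcodeCutoffs(2.4), "two class means")
})

test_that("Gaussian ROI fitting recovers the histogram mean", {
  set.seed(51)
  v <- rnorm(292, mean = 2.40, sd = 0.06 * 2.40)
  fit <- fitGaussianHistogram(v)
  expect_true(fit$converged)
  expect_lt(abs(fit$mean - 2.40), 0.05)
  expect_error(fitGaussianHistogram(rnorm(5)), "at least 10")
})

test_that("beads drawn at the printed CV are classified to the correct
          barcode almost surely", {
  set.seed(52)
  n_trials <- 200
  cls <- integer(n_trials)
  for (i in seq_len(n_trials)) {
    roi <- list(rnorm(292, 2.40, 0.06 * 2.40))
    res <- classifyBarcodes(roi, c(1.90, 2.40, 3.50))
    cls[i] <- res$assignment[1]
  }
  expect_gte(mean(cls == 2L, na.rm = TRUE), 0.99)
})

test_that("classification flags degenerate ROIs instead of guessing", {
  roi <- list(rep(2.4, 20))   # zero-width histogram
  res <- classifyBarcodes(roi, c(1.90, 2.40, 3.50))
  expect_true(res$unclassified[1] || res$assignment[1] == 2L)
})

test_that("FRET efficiency follows the donor-quenching formula and
          round-trips", {
  expect_equal(fretEfficiency(2.5, 2.5), 0)
  expect_equal(fretEfficiency(2.50, 2.30), 0.08)
  expect_error(fretEfficiency(0, 1), "positive")
  expect_equal(fretEfficiencyIntensity(100, 92), 0.08)
  # round trip: tau_da = tau_d (1 - E) recovers E exactly
  E <- 0.057; tau_d <- 2.6
  expect_equal(fretEfficiency(tau_d, tau_d * (1 - E)), E)
  # printed band: donor-lifetime changes of 0.04-0.20 ns with tau_d in
  # the CFP range map into efficiencies of roughly 0.02-0.07
  expect_equal(fretEfficiency(2.0, 2.0 - 0.04), 0.02)
  expect_lt(abs(fretEfficiency(2.9, 2.9 - 0.20) - 0.069), 0.001)
})

test_that("sigmoid response fit recovers exact and noisy 4PL data", {
  conc <- c(0, 0.5, 1, 2, 5, 10, 15)
  truth <- list(lo = 0.02, hi = 0.065, mid = 3.5, k = 0.9)
  f <- function(c) truth$lo + (truth$hi - truth$lo) /
    (1 + exp(-truth$k * (c - truth$mid)))
  fit <- fitGlucoseResponse(conc, f(conc))
  expect_true(fit$converged)
  expect_gt(fit$r_squared, 1 - 1e-9)
  expect_lt(abs(fit$floor - truth$lo), 1e-6)
  expect_lt(abs(fit$ceiling - truth$hi), 1e-6)
  expect_lt(abs(fit$mid - truth$mid), 1e-5)
  # constant data: no response, nothing explained
  flat <- fitGlucoseResponse(conc, rep(0.05, 7))
  expect_lt(abs(flat$r_squared), 1e-6)
  expect_error(fitGlucoseResponse(1:3, 1:3), "at least 4")
  # noisy Monte-Carlo recovery at the printed design points
  set.seed(53)
  recov <- replicate(100, {
    fit <- fitGlucoseResponse(conc, f(conc) + rnorm(7, sd = 0.005))
    c(fit$floor, fit$ceiling, fit$mid)
  })
  expect_lt(abs(mean(recov[1, ]) - truth$lo), 0.01)
  expect_lt(abs(mean(recov[2, ]) - truth$hi), 0.01)
  expect_lt(abs(median(recov[3, ]) - truth$mid), 1.5)
})

test_that("intensity segmentation labels a two-blob fixture exactly", {
  img <- matrix(0, 10, 12)
  img[2:4, 2:4] <- 5      # mitochondria blob
  img[6:9, 6:10] <- 1     # dim cell body
  nuc <- matrix(FALSE, 10, 12); nuc[8:9, 9:10] <- TRUE
  lab <- segmentByIntensity(img, threshold = 3, nuclei_mask = nuc)
  expect_true(all(lab[2:4, 2:4] == "mitochondria"))
  expect_true(all(lab[6:7, 6:8] == "cytoplasm"))
  expect_true(all(lab[nuc] == "nuclei"))
  expect_true(all(lab[img == 0 & !nuc] == "background"))
  # threshold at the minimum labels the whole cell mitochondria
  lab2 <- segmentByIntensity(img, threshold = min(img[img > 0]))
  expect_true(all(lab2[img > 0] == "mitochondria"))
  expect_warning(segmentByIntensity(img, threshold = max(img) + 1),
                 "empty mitochondrial")
})

test_that("FLIRR map is the amplitude ratio with nuclei and undefined
          pixels masked", {
  a2 <- matrix(0.3, 6, 6)
  a1 <- matrix(0.3, 6, 6)
  res <- flirrMap(a2, a1)
  expect_true(all(res$flirr == 1))
  # synthetic cell: mitochondrial FLIRR planted in the 0.2-0.4 band
  set.seed(54)
  a1 <- matrix(0.5, 8, 10)
  seg <- matrix("cytoplasm", 8, 10)
  seg[2:4, 2:5] <- "mitochondria"
  seg[6:7, 7:9] <- "nuclei"
  seg[1, ] <- "background"
  target <- matrix(0.6, 8, 10)
  target[seg == "mitochondria"] <- runif(sum(seg == "mitochondria"),
                                         0.2, 0.4)
  a2 <- target * a1
  res2 <- flirrMap(a2, a1, segmentation = seg)
  expect_true(all(is.na(res2$flirr[seg %in% c("nuclei", "background")])))
  mito <- res2$regions$mitochondria
  expect_true(all(mito >= 0.2 & mito <= 0.4))
  expect_gte(median(res2$regions$cell_no_nuclei), median(mito))
  # undefined pixels (alpha1_fad = 0) are masked
  a1z <- a1; a1z[3, 3] <- 0
  res3 <- flirrMap(a2, a1z)
  expect_true(is.na(res3$flirr[3, 3]))
  expect_error(flirrMap(a2, matrix(1, 2, 2)), "equal shape")
})
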