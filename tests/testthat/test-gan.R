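# Contract tests for the three-stage training and inference surface,
# on a deliberately tiny library so each stage runs in seconds. The
# science-level checks (validation improvement, parameter recovery,
# baseline ordering) live in the acceptance suite with a larger budget.

tiny_lib <- buildTrainingLibrary(fk_irf,
                                 alpha_grid = c(0.3, 0.7, 1.0),
                                 tau1_grid = c(1.2, 1.8),
                                 tau2_grid = c(2.6, 3.4),
                                 rates = c(150, 1500), per_truth = 10L,
                                 thin_to = NULL, seed = 31L)

test_that("WGAN smoke run keeps losses finite and outputs valid pmfs", {
  res <- trainWGAN(tiny_lib, trainingSchedule("wgan", iters = 30L,
                                              seed = 32L,
                                              val_every = 10L))
  expect_true(all(is.finite(res$training_log$d_loss)))
  expect_true(all(is.finite(res$training_log$g_loss)))
  ns <- asNamespace("flimkit")
  X <- ns$.peakNormRows(tiny_lib@degraded[1:5, ])
  Xi <- matrix(ns$.irfInputRow(fk_irf), 5, 256, byrow = TRUE)
  Y <- ns$.gForward(res$g_weights, X, Xi, res$g_spec)$Y
  expect_true(all(Y >= 0))
  expect_equal(rowSums(Y), rep(1, 5), tolerance = 1e-6)
})

test_that("estimator training is deterministic and respects the
          degenerate single-component limit", {
  e1 <- trainEstimator(tiny_lib, trainingSchedule("estimator",
                                                  iters = 1500L,
                                                  seed = 33L))
  e2 <- trainEstimator(tiny_lib, trainingSchedule("estimator",
                                                  iters = 1500L,
                                                  seed = 33L))
  expect_identical(e1$e_weights, e2$e_weights)
  ns <- asNamespace("flimkit")
  # a training pmf with alpha1 = 1: predicted tau_a collapses onto tau1
  i <- which(alpha1(truthParams(tiny_lib)) == 1)[1]
  Xi <- matrix(ns$.irfInputRow(fk_irf), 1, 256, byrow = TRUE)
  O <- ns$.eForward(e1$e_weights,
                    tiny_lib@pmfs[i, , drop = FALSE], Xi)$O
  ts <- e1$tau_scale
  pr <- lifetimeParams(O[1], O[2] * ts, O[3] * ts)
  expect_lt(abs(apparentLifetime(pr) - tau1(pr)), binWidth(fk_grid))
})

test_that("combination training yields a guarded, pure, batch-consistent
          bundle", {
  g <- trainWGAN(tiny_lib, trainingSchedule("wgan", iters = 40L,
                                            seed = 34L, val_every = 10L))
  e <- trainEstimator(tiny_lib, trainingSchedule("estimator",
                                                 iters = 800L,
                                                 seed = 35L))
  bundle <- trainCombined(g, e, tiny_lib,
                          trainingSchedule("combined", iters = 60L,
                                           seed = 36L, val_every = 20L))
  expect_s4_class(bundle, "NetworkBundle")
  # combination training never harms the held-out loss (checkpointed)
  hl <- bundle@training_log$hold_loss
  expect_lte(min(hl[-1], na.rm = TRUE), hl[1] + 1e-12)

  h <- sampleDecay(tiny_lib@pmfs[1, ], 1500, fk_grid, seed = 37)
  p1 <- inferPixel(bundle, h, fk_irf)
  expect_s4_class(p1, "LifetimeParams")
  expect_true(tau1(p1) <= tau2(p1) && alpha1(p1) >= 0 && alpha1(p1) <= 1)
  # identical pixels give identical parameters (pure function)
  p2 <- inferPixel(bundle, h, fk_irf)
  expect_identical(p1@alpha1, p2@alpha1)

  # mismatched-IRF fingerprints are refused unless overridden
  other <- gaussianIRF(fk_grid, fwhm = 0.8, onset = 7)
  expect_error(inferPixel(bundle, h, other), "fingerprint")
  expect_s4_class(inferPixel(bundle, h, other, override_irf = TRUE),
                  "LifetimeParams")
  expect_error(inferPixel(bundle,
                          decayHistogram(integer(256), fk_grid),
                          fk_irf), "empty")

  # batch inference over a cube equals the pixel-by-pixel map exactly
  pat <- list(alpha1 = matrix(0.7, 2, 2), tau1 = matrix(1.2, 2, 2),
              tau2 = matrix(3.4, 2, 2))
  cube <- simulateBenchmarkImage(pat, rate = 300, irf = fk_irf,
                                 seed = 38)
  maps <- inferImage(bundle, cube, fk_irf)
  for (i in 1:2) for (j in 1:2) {
    pp <- inferPixel(bundle, cubePixel(cube, i, j), fk_irf)
    expect_equal(maps$tau_apparent[i, j], apparentLifetime(pp),
                 tolerance = 1e-12)
  }

  # bundle serialization round-trips weights and guards
  path <- tempfile(fileext = ".rds")
  saveBundle(bundle, path)
  b2 <- loadBundle(path)
  expect_identical(b2@weights, bundle@weights)
  expect_identical(b2@irf_fingerprint, bundle@irf_fingerprint)
  p3 <- inferPixel(b2, h, fk_irf)
  expect_identical(p3@tau1, p1@tau1)
})

test_that("training schedules validate their inputs", {
  expect_error(trainingSchedule("wgan", clip_value = 0), "clip_value")
  expect_error(trainingSchedule("wgan", g_lr = -1))
  s <- trainingSchedule("estimator", iters = 10L)
  expect_equal(s$stage, "estimator")
  expect_equal(s$e_lr, 1e-3)
  expect_equal(s$d_lr, 5e-5)
  expect_equal(s$g_lr, 1e-4)
})
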