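# flimkit

Fluorescence lifetime imaging microscopy (FLIM) reads out, at every
pixel, how fast fluorescence decays rather than how bright it is —
contrast that is immune to fluorophore concentration and excitation
power. The catch is the analysis: at realistic scan speeds a pixel may
collect only 50–200 photons, and the classical ways of turning a
photon-arrival histogram into a lifetime either get slow
(maximum-likelihood fitting) or unreliable (least-squares and
frequency-domain fitting on Poisson-starved data).

`flimkit` is an R toolkit for this problem, aimed at microscopists and
methods developers. It provides:

* **Simulation** of time-correlated single-photon-counting (TCSPC)
  decay histograms: a two-component decay
  `m(t) = α₁ e^(−t/τ₁) + (1−α₁) e^(−t/τ₂)` convolved with an
  instrument response function (IRF) on a periodic 256-bin / 50 ns
  axis, photon-sampled as Poisson totals spread multinomially
  (`decayPmf()`, `sampleDecay()`, `buildTrainingLibrary()`,
  `simulateBenchmarkImage()`).
* **Classical per-pixel estimators**: weighted least squares
  (`fitTDLSE()`), multinomial maximum likelihood (`fitTDMLE()`), and
  multi-harmonic phasor least squares (`fitDFDLSE()`), plus phasor
  utilities (`decayPhasor()`, `irfCorrectPhasor()`, `tauPhase()`,
  `tauMod()`).
* **An adversarial restorer**: a Wasserstein-GAN stack — generator,
  critic, estimator, implemented and backpropagated in base R — that
  learns to map photon-starved decays to lifetime parameters
  (`trainWGAN()`, `trainEstimator()`, `trainCombined()`,
  `inferPixel()`, `inferImage()`). Estimates report the apparent
  lifetime `τα = α₁τ₁ + (1−α₁)τ₂`.
* **Preprocessing**: center-of-mass onset alignment (`comeAlign()`)
  that makes estimates invariant to instrument onset drift.
* **Downstream analyses**: lifetime-barcode classification with
  midpoint cutoffs (`classifyBarcodes()`), FRET efficiency
  `E = 1 − τ_DA/τ_D` and sigmoidal sensor-response fitting
  (`fretEfficiency()`, `fitGlucoseResponse()`), the FLIRR metabolic
  index `α₂^NAD(P)H / α₁^FAD` (`flirrMap()`,
  `segmentByIntensity()`), and image-quality metrics MSE / PSNR /
  SSIM / VIF (`qualityReport()`).

See `vignettes/flimkit-methods.Rmd` for the models, numerical choices
and limitations.

## A worked example

Simulate one photon-starved pixel and estimate it three ways:

```r
library(flimkit)

grid  <- histogramGrid()                      # 256 bins over 50 ns
irf   <- gaussianIRF(grid, fwhm = 0.5, onset = 5)
truth <- lifetimeParams(0.5, 1.2, 3.2)        # tau_alpha = 2.20 ns
pmf   <- decayPmf(truth, irf)
h     <- sampleDecay(pmf, rate = 50, grid, seed = 7)   # 66 photons drawn

apparentLifetime(fitTDMLE(h, irf))
#> [1] 0.765513
apparentLifetime(fitTDLSE(h, irf))
#> [1] 1.28522
apparentLifetime(fitDFDLSE(h, irf))
#> [1] 2.213478
```

At ~66 photons a single pixel is simply hard: here the
maximum-likelihood and least-squares estimates land far from the true
2.20 ns while the phasor fit happens to get lucky — over many pixels
all three scatter widely (on 250 such pixels their apparent-lifetime
mean squared errors come out around 0.6, 1.0 and 1.3 ns²
respectively). That scatter is the low-count failure mode the
adversarial restorer addresses. Training the stack on a small library
and applying it to the same pixel:

```r
lib <- buildTrainingLibrary(irf,
         alpha_grid = seq(0.1, 0.9, length.out = 5),
         tau1_grid  = seq(1.0, 2.2, length.out = 5),
         tau2_grid  = seq(2.4, 4.0, length.out = 5),
         rates = c(50, 150, 600, 1500), per_truth = 40, thin_to = 50,
         seed = 11)
g  <- trainWGAN(lib, trainingSchedule("wgan", iters = 2000, seed = 21,
                                      patience = 600))
e  <- trainEstimator(lib, trainingSchedule("estimator", iters = 4000,
                                           seed = 22))
bd <- trainCombined(g, e, lib, trainingSchedule("combined",
                                                iters = 1200, seed = 23))
apparentLifetime(inferPixel(bd, h, irf))
#> [1] 2.12533
```

The restored estimate sits within 0.08 ns of the truth, and on the
same 250 low-count pixels the stack's mean squared error is about
0.14 ns² — several-fold below every classical baseline. (Training
takes a few minutes on one CPU; the bundle is reusable for any decay
acquired under the same IRF, and refuses other IRFs by fingerprint.)

A shell entry point with `simulate` / `estimate` / `metrics` /
`benchmark` subcommands is installed at
`system.file("scripts", "flimkit", package = "flimkit")`.

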