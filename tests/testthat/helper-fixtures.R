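# Shared fixtures, built in code at test time.

fk_grid <- histogramGrid()          # 256 bins over 50 ns
fk_irf <- gaussianIRF(fk_grid, fwhm = 0.5, onset = 5)

# Independent fine-grid pmf oracle (x64 oversampling, numerical
# quadrature for the model windows, direct FFT convolution): a separate
# code path from decayPmf.
fk_pmf_oracle <- function(a, t1, t2, fwhm = 0.5, onset = 5, nb = 256,
                          Tp = 50, os = 64) {
  M <- nb * os
  ws <- Tp / M
  sg <- fwhm / (2 * sqrt(2 * log(2)))
  edges <- ((0:M) - 0.5) * ws
  ir <- 0
  for (j in -1:1) ir <- ir + diff(pnorm((edges - onset - j * Tp) / sg))
  ir <- ir / sum(ir)
  # model mass over [j ws, (j+1) ws) by cumulative-trapezoid quadrature
  nsub <- 16
  tt <- seq(0, Tp, length.out = M * nsub + 1)
  vals <- a * exp(-tt / t1) + (1 - a) * exp(-tt / t2)
  ct <- cumsum(c(0, (vals[-1] + vals[-length(vals)]) / 2 * diff(tt)))
  marks <- seq(1, M * nsub + 1, by = nsub)
  m <- diff(ct[marks])
  cv <- Re(fft(fft(ir) * fft(m), inverse = TRUE)) / M
  p <- colSums(matrix(cv, nrow = os))
  p / sum(p)
}

# Small training library in the 1-4 ns lifetime range (50 ground truths).
fk_small_lib <- function(per_truth = 40L, seed = 11L,
                         rates = c(50, 150, 600, 1500)) {
  buildTrainingLibrary(fk_irf,
                       alpha_grid = seq(0.1, 0.9, length.out = 5),
                       tau1_grid = seq(1.0, 2.2, length.out = 5),
                       tau2_grid = seq(2.4, 4.0, length.out = 5),
                       rates = rates, per_truth = per_truth,
                       thin_to = 50L, seed = seed)
}

# Numeric gradient check helper: max relative error between analytic
# gradients and central differences over a few entries per tensor.
fk_grad_check <- function(loss_fn, weights, grads, n_per = 4L,
                          eps = 1e-6) {
  relerr <- c()
  for (nm in names(grads)) {
    w2 <- weights
    idx <- sample(length(w2[[nm]]), min(n_per, length(w2[[nm]])))
    for (i in idx) {
      w2[[nm]][i] <- weights[[nm]][i] + eps
      fp <- loss_fn(w2)
      w2[[nm]][i] <- weights[[nm]][i] - eps
      fm <- loss_fn(w2)
      w2[[nm]][i] <- weights[[nm]][i]
      num <- (fp - fm) / (2 * eps)
      an <- grads[[nm]][i]
      relerr <- c(relerr, abs(num - an) / max(abs(num) + abs(an), 1e-8))
    }
  }
  max(relerr)
}
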