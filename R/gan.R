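# The adversarial decay-restoration stack: a convolutional generator G
# that maps a photon-starved (peak-normalized) decay plus the IRF to a
# high-count-mimicking area-normalized decay, a Wasserstein critic D,
# and an estimator E mapping restored decays to lifetime parameters.
# Training follows the three-stage protocol: (1) WGAN training of G and
# D with weight clipping, (2) supervised training of E on ground-truth
# pmfs, (3) end-to-end fine-tuning of G∘E with an MSE loss.

#' Generator architecture specification
#'
#' Two convolutional blocks (conv + average pooling of stride four),
#' a flatten layer, a multi-task layer producing three virtual lifetime
#' parameters (ReLU), and two fully connected decoding layers (the last
#' with tanh) whose output is rectified and area-renormalized. Learnable
#' skip connections pass data between layers of matching resolution
#' (pooled first-block features into the first decoding layer, and the
#' input into the output layer through a projection), so the decoder
#' sees detail without the restored histogram inheriting the raw input's
#' shot noise additively.
#'
#' @param input_len histogram length (default 256).
#' @param kernel convolution kernel width (default 8).
#' @param channels channel counts of the two conv blocks (default 16, 32).
#' @param pool_stride average-pooling stride (default 4).
#' @param virtual width of the multi-task virtual-parameter layer.
#' @param decode width of the first decoding layer.
#' @return a list spec.
#' @export
generatorSpec <- function(input_len = 256L, kernel = 8L,
                          channels = c(16L, 32L), pool_stride = 4L,
                          virtual = 3L, decode = 64L) {
  list(input_len = as.integer(input_len), kernel = as.integer(kernel),
       channels = as.integer(channels), pool_stride = as.integer(pool_stride),
       virtual = as.integer(virtual), decode = as.integer(decode))
}

#' Critic (discriminator) architecture specification
#'
#' Four fully connected layers of 128, 64, 8 and 1 nodes; sigmoid
#' activations on the first three, linear output (unbounded critic
#' score).
#'
#' @param widths layer widths.
#' @return a list spec.
#' @export
discriminatorSpec <- function(widths = c(128L, 64L, 8L, 1L)) {
  list(widths = as.integer(widths))
}

#' Estimator architecture specification
#'
#' Two fully connected input branches (128 nodes for the decay, 64 for
#' the IRF), concatenation, and a multi-task layer (ReLU) with one
#' sigmoid head per output parameter (alpha1, tau1, tau2; lifetimes in
#' tau_scale-normalized units).
#'
#' @param branch widths of the decay and IRF branches.
#' @param head_hidden hidden width of each task head.
#' @return a list spec.
#' @export
estimatorSpec <- function(branch = c(128L, 64L), head_hidden = 32L) {
  list(branch = as.integer(branch), head_hidden = as.integer(head_hidden))
}

#' Training schedule for the three-stage protocol
#'
#' Learning rates follow the published protocol: Adam 1e-4 for the
#' generator, RMSprop 5e-5 for the critic, Adam 1e-3 for the estimator
#' and the combination stage. Unstated hyperparameters (critic steps per
#' generator step, clip bound, batch size) default to standard WGAN
#' practice and are configurable.
#'
#' @param stage one of "wgan", "estimator", "combined".
#' @param iters training iterations (generator iterations for "wgan").
#' @param batch_size minibatch size (default 64).
#' @param seed integer seed; training is deterministic given it.
#' @param g_lr,d_lr,e_lr learning rates.
#' @param critic_steps critic updates per generator update (default 5).
#' @param clip_value critic weight-clip bound (default 0.01).
#' @param val_every validation cadence in iterations.
#' @param patience early-stopping patience in iterations.
#' @param val_frac fraction of degraded decays held out for validation.
#' @return a list schedule.
#' @export
trainingSchedule <- function(stage = c("wgan", "estimator", "combined"),
                             iters = 1000L, batch_size = 64L, seed = 1L,
                             g_lr = 1e-4, d_lr = 5e-5, e_lr = 1e-3,
                             critic_steps = 5L, clip_value = 0.01,
                             val_every = 25L, patience = 200L,
                             val_frac = 0.1) {
  stage <- match.arg(stage)
  stopifnot(g_lr > 0, d_lr > 0, e_lr > 0, iters >= 1, batch_size >= 1)
  if (stage == "wgan" && clip_value <= 0)
    stop("clip_value must be positive in the wgan stage")
  list(stage = stage, iters = as.integer(iters),
       batch_size = as.integer(batch_size), seed = as.integer(seed),
       g_lr = g_lr, d_lr = d_lr, e_lr = e_lr,
       critic_steps = as.integer(critic_steps), clip_value = clip_value,
       val_every = as.integer(val_every), patience = as.integer(patience),
       val_frac = val_frac)
}

# ---- weight construction ----

.gInit <- function(spec) {
  K <- spec$kernel; ch <- spec$channels; L <- spec$input_len
  L1 <- L %/% spec$pool_stride
  flat <- (L %/% (spec$pool_stride^2)) * ch[2]
  list(cW1 = .initConv(K, 2L, ch[1]), cb1 = numeric(ch[1]),
       cW2 = .initConv(K, ch[1], ch[2]), cb2 = numeric(ch[2]),
       hW = .initMat(flat, spec$virtual), hb = numeric(spec$virtual),
       d1W = .initMat(spec$virtual, spec$decode), d1b = numeric(spec$decode),
       d2W = .initMat(spec$decode, L, gain = 1), d2b = numeric(L),
       # skip connections between layers of matching resolution:
       # pooled level-1 features -> first decode layer, input -> output
       s1W = .initMat(L1 * ch[1], spec$decode, gain = 0.5),
       s2W = .initMat(L, L, gain = 0.2))
}

.dInit <- function(spec, input_len) {
  w <- list()
  nin <- input_len
  for (i in seq_along(spec$widths)) {
    w[[paste0("W", i)]] <- .initMat(nin, spec$widths[i], gain = 1)
    w[[paste0("b", i)]] <- numeric(spec$widths[i])
    nin <- spec$widths[i]
  }
  w
}

.eInit <- function(spec, input_len) {
  w <- list(b1W = .initMat(input_len, spec$branch[1]),
            b1b = numeric(spec$branch[1]),
            b2W = .initMat(input_len, spec$branch[2]),
            b2b = numeric(spec$branch[2]))
  nc <- sum(spec$branch)
  for (j in 1:3) {
    w[[paste0("h", j, "W")]] <- .initMat(nc, spec$head_hidden)
    w[[paste0("h", j, "b")]] <- numeric(spec$head_hidden)
    w[[paste0("o", j, "W")]] <- .initMat(spec$head_hidden, 1L, gain = 1)
    w[[paste0("o", j, "b")]] <- numeric(1L)
  }
  w
}

# ---- generator forward / backward ----

.gForward <- function(w, Xd, Xi, spec) {
  B <- nrow(Xd); L <- spec$input_len; ps <- spec$pool_stride
  L1 <- L %/% ps; L2 <- L1 %/% ps
  X0 <- cbind(as.vector(Xd), as.vector(Xi))   # (B*L) x 2, r = b+(l-1)B
  c1 <- .convF(X0, w$cW1, w$cb1, B, L)
  M1 <- c1$out > 0
  P1 <- .poolF(c1$out * M1, B, L, ps)
  c2 <- .convF(P1, w$cW2, w$cb2, B, L1)
  M2 <- c2$out > 0
  P2 <- .poolF(c2$out * M2, B, L1, ps)
  Fm <- matrix(P2, B)
  Fm1 <- matrix(P1, B)            # level-1 features for the skip path
  Hz <- .denseF(Fm, w$hW, w$hb); Mh <- Hz > 0; V <- Hz * Mh
  D1z <- .denseF(V, w$d1W, w$d1b) + Fm1 %*% w$s1W
  Md1 <- D1z > 0; D1 <- D1z * Md1
  D2 <- tanh(.denseF(D1, w$d2W, w$d2b) + Xd %*% w$s2W)
  MS <- D2 > 0
  R <- D2 * MS
  denom <- rowSums(R) + 1e-8
  Y <- R / denom
  list(Y = Y, cache = list(Xd = Xd, c1 = c1, M1 = M1, P1 = P1,
                           c2 = c2, M2 = M2, P2 = P2, Fm = Fm, Fm1 = Fm1,
                           Mh = Mh, V = V, Md1 = Md1, D1 = D1, D2 = D2,
                           MS = MS, denom = denom, Y = Y, B = B))
}

.gBackward <- function(w, cache, dY, spec) {
  B <- cache$B; L <- spec$input_len; ps <- spec$pool_stride
  L1 <- L %/% ps
  sY <- rowSums(dY * cache$Y)
  dR <- (dY - sY) / cache$denom
  dS <- dR * cache$MS
  dD2z <- dS * (1 - cache$D2^2)
  bd2 <- .denseB(cache$D1, w$d2W, dD2z)
  ds2W <- crossprod(cache$Xd, dD2z)
  dD1z <- bd2$dX * cache$Md1
  bd1 <- .denseB(cache$V, w$d1W, dD1z)
  ds1W <- crossprod(cache$Fm1, dD1z)
  dFm1 <- tcrossprod(dD1z, w$s1W)
  dHz <- bd1$dX * cache$Mh
  bh <- .denseB(cache$Fm, w$hW, dHz)
  dP2 <- matrix(bh$dX, nrow = nrow(cache$P2))
  dR2 <- .poolB(dP2, B, L1, ps)
  dZ2 <- dR2 * cache$M2
  bc2 <- .convB(cache$c2, w$cW2, dZ2, B, L1)
  dP1 <- bc2$dX + matrix(dFm1, nrow = nrow(cache$P1))
  dR1 <- .poolB(dP1, B, L, ps)
  dZ1 <- dR1 * cache$M1
  bc1 <- .convB(cache$c1, w$cW1, dZ1, B, L)
  list(cW1 = bc1$dW, cb1 = bc1$db, cW2 = bc2$dW, cb2 = bc2$db,
       hW = bh$dW, hb = bh$db, d1W = bd1$dW, d1b = bd1$db,
       d2W = bd2$dW, d2b = bd2$db, s1W = ds1W, s2W = ds2W)
}

# ---- critic forward / backward ----

.dForward <- function(w, X) {
  Z1 <- .denseF(X, w$W1, w$b1); A1 <- .nnSigmoid(Z1)
  Z2 <- .denseF(A1, w$W2, w$b2); A2 <- .nnSigmoid(Z2)
  Z3 <- .denseF(A2, w$W3, w$b3); A3 <- .nnSigmoid(Z3)
  Z4 <- .denseF(A3, w$W4, w$b4)
  list(score = drop(Z4), cache = list(X = X, A1 = A1, A2 = A2, A3 = A3))
}

.dBackward <- function(w, cache, dscore) {
  dZ4 <- matrix(dscore, ncol = 1)
  b4 <- .denseB(cache$A3, w$W4, dZ4)
  dZ3 <- b4$dX * cache$A3 * (1 - cache$A3)
  b3 <- .denseB(cache$A2, w$W3, dZ3)
  dZ2 <- b3$dX * cache$A2 * (1 - cache$A2)
  b2 <- .denseB(cache$A1, w$W2, dZ2)
  dZ1 <- b2$dX * cache$A1 * (1 - cache$A1)
  b1 <- .denseB(cache$X, w$W1, dZ1)
  list(grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
                    W3 = b3$dW, b3 = b3$db, W4 = b4$dW, b4 = b4$db),
       dX = b1$dX)
}

# ---- estimator forward / backward ----

.eForward <- function(w, Xd, Xi) {
  H1z <- .denseF(Xd, w$b1W, w$b1b); H1 <- pmax(H1z, 0)
  H2z <- .denseF(Xi, w$b2W, w$b2b); H2 <- pmax(H2z, 0)
  Hc <- cbind(H1, H2)
  O <- matrix(0, nrow(Xd), 3L)
  heads <- vector("list", 3L)
  for (j in 1:3) {
    Gz <- .denseF(Hc, w[[paste0("h", j, "W")]], w[[paste0("h", j, "b")]])
    G <- pmax(Gz, 0)
    Oz <- .denseF(G, w[[paste0("o", j, "W")]], w[[paste0("o", j, "b")]])
    O[, j] <- .nnSigmoid(drop(Oz))
    heads[[j]] <- list(Gz = Gz, G = G, o = O[, j])
  }
  list(O = O, cache = list(Xd = Xd, Xi = Xi, H1z = H1z, H1 = H1,
                           H2z = H2z, H2 = H2, Hc = Hc, heads = heads))
}

.eBackward <- function(w, cache, dO) {
  n1 <- ncol(cache$H1)
  grads <- list()
  dHc <- cache$Hc * 0
  for (j in 1:3) {
    hd <- cache$heads[[j]]
    dOz <- matrix(dO[, j] * hd$o * (1 - hd$o), ncol = 1)
    bo <- .denseB(hd$G, w[[paste0("o", j, "W")]], dOz)
    dGz <- bo$dX * (hd$Gz > 0)
    bh <- .denseB(cache$Hc, w[[paste0("h", j, "W")]], dGz)
    grads[[paste0("o", j, "W")]] <- bo$dW
    grads[[paste0("o", j, "b")]] <- bo$db
    grads[[paste0("h", j, "W")]] <- bh$dW
    grads[[paste0("h", j, "b")]] <- bh$db
    dHc <- dHc + bh$dX
  }
  dH1z <- dHc[, seq_len(n1), drop = FALSE] * (cache$H1z > 0)
  dH2z <- dHc[, -seq_len(n1), drop = FALSE] * (cache$H2z > 0)
  b1 <- .denseB(cache$Xd, w$b1W, dH1z)
  b2 <- .denseB(cache$Xi, w$b2W, dH2z)
  grads$b1W <- b1$dW; grads$b1b <- b1$db
  grads$b2W <- b2$dW; grads$b2b <- b2$db
  list(grads = grads, dXd = b1$dX)
}

# ---- data preparation helpers ----

.peakNormRows <- function(M) {
  mx <- apply(M, 1, max)
  mx[mx <= 0] <- 1
  M / mx
}

.irfInputRow <- function(irf) {
  w <- irfWeights(irf)
  w / max(w)
}

# ---- stage 1: WGAN ----

#' Stage-1 adversarial training of the generator and critic
#'
#' Trains G and D with the Wasserstein loss: the critic maximizes
#' `mean D(real) - mean D(G(degraded))` (weights clipped to
#' `[-c, c]` after every step, `critic_steps` critic updates per
#' generator update), and the generator maximizes the critic score of
#' its outputs. Real examples are area-normalized ground-truth pmfs,
#' generator inputs are peak-normalized degraded decays plus the IRF.
#' A held-out validation split tracks the mean squared distance between
#' restored decays and their parent pmfs; the checkpoint with the best
#' validation loss is returned (early stopping).
#'
#' @param lib a [TrainingLibrary-class].
#' @param sched a [trainingSchedule()] with `stage = "wgan"`.
#' @param g_spec,d_spec architecture specs.
#' @return list with `g_weights`, `d_weights`, `g_spec`, `d_spec`,
#'   `training_log` (iter, d_loss, g_loss, val_l2), `best_iter`,
#'   `best_val`.
#' @export
trainWGAN <- function(lib, sched = trainingSchedule("wgan"),
                      g_spec = generatorSpec(nBins(lib@irf)),
                      d_spec = discriminatorSpec()) {
  if (!nrow(lib@degraded)) stop("training library is empty")
  nonzero <- rowSums(lib@degraded) > 0
  Xdeg <- .peakNormRows(lib@degraded[nonzero, , drop = FALSE])
  parent <- lib@parent[nonzero]
  P <- lib@pmfs
  xi <- .irfInputRow(lib@irf)
  .withSeed(sched$seed, {
    n <- nrow(Xdeg)
    n_val <- max(1L, round(sched$val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    gw <- .gInit(g_spec)
    dw <- .dInit(d_spec, g_spec$input_len)
    g_state <- .optInit(gw)
    d_state <- .optInit(dw)
    B <- sched$batch_size
    Xi_b <- matrix(xi, B, length(xi), byrow = TRUE)
    Xi_val <- matrix(xi, n_val, length(xi), byrow = TRUE)
    Pval <- P[parent[val_idx], , drop = FALSE]
    Xval <- Xdeg[val_idx, , drop = FALSE]
    log_d <- log_g <- log_v <- rep(NA_real_, sched$iters)
    best <- list(val = Inf, iter = 0L, gw = gw)
    last_improve <- 0L
    n_done <- 0L
    for (t in seq_len(sched$iters)) {
      d_loss <- NA_real_
      # G is fixed during the critic's inner loop, so one fake batch per
      # iteration serves all critic steps (fresh real batches each step).
      fidx <- sample(tr_idx, B, replace = TRUE)
      fakeY <- .gForward(gw, Xdeg[fidx, , drop = FALSE], Xi_b, g_spec)$Y
      for (cs in seq_len(sched$critic_steps)) {
        ridx <- sample(nrow(P), B, replace = TRUE)
        fr <- .dForward(dw, fakeY)
        rr <- .dForward(dw, P[ridx, , drop = FALSE])
        d_loss <- mean(fr$score) - mean(rr$score)
        gf <- .dBackward(dw, fr$cache, rep(1 / B, B))$grads
        gr <- .dBackward(dw, rr$cache, rep(-1 / B, B))$grads
        gsum <- Map(`+`, gf, gr)
        up <- .rmspropStep(dw, gsum, d_state, sched$d_lr)
        dw <- .clipWeights(up$weights, sched$clip_value)
        d_state <- up$state
      }
      fidx <- sample(tr_idx, B, replace = TRUE)
      fake <- .gForward(gw, Xdeg[fidx, , drop = FALSE], Xi_b, g_spec)
      fs <- .dForward(dw, fake$Y)
      g_loss <- -mean(fs$score)
      if (!is.finite(d_loss) || !is.finite(g_loss))
        stop(sprintf("training diverged (non-finite loss) at iteration %d", t))
      dY <- .dBackward(dw, fs$cache, rep(-1 / B, B))$dX
      ggr <- .gBackward(gw, fake$cache, dY, g_spec)
      up <- .adamStep(gw, ggr, g_state, sched$g_lr, t)
      gw <- up$weights; g_state <- up$state
      val_l2 <- NA_real_
      if (t %% sched$val_every == 0L || t == sched$iters) {
        vout <- .gForward(gw, Xval, Xi_val, g_spec)$Y
        val_l2 <- mean(rowSums((vout - Pval)^2))
        if (val_l2 < best$val) {
          best <- list(val = val_l2, iter = t, gw = gw)
          last_improve <- t
        }
      }
      log_d[t] <- d_loss; log_g[t] <- g_loss; log_v[t] <- val_l2
      n_done <- t
      if (t - last_improve >= sched$patience && best$iter > 0L) break
    }
    log <- data.frame(iter = seq_len(n_done), d_loss = log_d[seq_len(n_done)],
                      g_loss = log_g[seq_len(n_done)],
                      val_l2 = log_v[seq_len(n_done)])
    list(g_weights = best$gw, d_weights = dw, g_spec = g_spec,
         d_spec = d_spec, training_log = log, best_iter = best$iter,
         best_val = best$val)
  })
}

# ---- stage 2: estimator ----

#' Stage-2 supervised training of the estimator on ground truths
#'
#' Trains E to map area-normalized ground-truth pmfs (plus the IRF) to
#' their parameter triples with an MSE loss (Adam). Lifetimes are
#' scaled to [0, 1] by the library's maximum tau2 before the loss.
#'
#' @param lib a [TrainingLibrary-class].
#' @param sched a [trainingSchedule()] with `stage = "estimator"`.
#' @param e_spec architecture spec.
#' @return list with `e_weights`, `e_spec`, `tau_scale`, `training_log`.
#' @export
trainEstimator <- function(lib, sched = trainingSchedule("estimator",
                                                         iters = 4000L),
                           e_spec = estimatorSpec()) {
  P <- lib@pmfs
  if (!nrow(P)) stop("training library has no ground truths")
  tau_scale <- max(tau2(truthParams(lib)))
  Tmat <- cbind(alpha1(truthParams(lib)),
                tau1(truthParams(lib)) / tau_scale,
                tau2(truthParams(lib)) / tau_scale)
  xi <- .irfInputRow(lib@irf)
  .withSeed(sched$seed, {
    ew <- .eInit(e_spec, ncol(P))
    e_state <- .optInit(ew)
    B <- min(sched$batch_size, nrow(P))
    Xi_b <- matrix(xi, B, length(xi), byrow = TRUE)
    log <- data.frame(iter = integer(0), loss = numeric(0))
    for (t in seq_len(sched$iters)) {
      idx <- sample(nrow(P), B, replace = TRUE)
      fw <- .eForward(ew, P[idx, , drop = FALSE], Xi_b)
      err <- fw$O - Tmat[idx, , drop = FALSE]
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at iteration %d", t))
      dO <- 2 * err / length(err)
      bk <- .eBackward(ew, fw$cache, dO)
      up <- .adamStep(ew, bk$grads, e_state, sched$e_lr, t)
      ew <- up$weights; e_state <- up$state
      if (t %% 100L == 0L || t == sched$iters)
        log <- rbind(log, data.frame(iter = t, loss = loss))
    }
    list(e_weights = ew, e_spec = e_spec, tau_scale = tau_scale,
         training_log = log)
  })
}

# ---- stage 3: combination ----

#' Stage-3 combination training of the generator-estimator stack
#'
#' Fine-tunes G and E end to end with an MSE loss between E(G(degraded))
#' and the true parameter triples (Adam, lr 1e-3). A held-out split of
#' degraded decays monitors the loss; the checkpoint with the best
#' held-out loss (including the pre-fine-tuning state) is kept, so
#' combination training never degrades held-out performance.
#'
#' @param g result of [trainWGAN()].
#' @param e result of [trainEstimator()].
#' @param lib the [TrainingLibrary-class].
#' @param sched a [trainingSchedule()] with `stage = "combined"`.
#' @return a [NetworkBundle-class] carrying the IRF fingerprint.
#' @export
trainCombined <- function(g, e, lib,
                          sched = trainingSchedule("combined",
                                                   iters = 1000L)) {
  nonzero <- rowSums(lib@degraded) > 0
  Xdeg <- .peakNormRows(lib@degraded[nonzero, , drop = FALSE])
  parent <- lib@parent[nonzero]
  tau_scale <- e$tau_scale
  Tmat <- cbind(alpha1(truthParams(lib)),
                tau1(truthParams(lib)) / tau_scale,
                tau2(truthParams(lib)) / tau_scale)
  xi <- .irfInputRow(lib@irf)
  g_spec <- g$g_spec
  .withSeed(sched$seed, {
    n <- nrow(Xdeg)
    n_hold <- max(1L, round(sched$val_frac * n))
    hold_idx <- sample.int(n, n_hold)
    tr_idx <- setdiff(seq_len(n), hold_idx)
    gw <- g$g_weights; ew <- e$e_weights
    g_state <- .optInit(gw); e_state <- .optInit(ew)
    B <- sched$batch_size
    Xi_b <- matrix(xi, B, length(xi), byrow = TRUE)
    Xi_h <- matrix(xi, n_hold, length(xi), byrow = TRUE)
    Xh <- Xdeg[hold_idx, , drop = FALSE]
    Th <- Tmat[parent[hold_idx], , drop = FALSE]
    holdLoss <- function(gw_, ew_) {
      Y <- .gForward(gw_, Xh, Xi_h, g_spec)$Y
      mean((.eForward(ew_, Y, Xi_h)$O - Th)^2)
    }
    best <- list(loss = holdLoss(gw, ew), gw = gw, ew = ew, iter = 0L)
    log <- data.frame(iter = 0L, loss = NA_real_, hold_loss = best$loss)
    for (t in seq_len(sched$iters)) {
      idx <- sample(tr_idx, B, replace = TRUE)
      gf <- .gForward(gw, Xdeg[idx, , drop = FALSE], Xi_b, g_spec)
      ef <- .eForward(ew, gf$Y, Xi_b)
      err <- ef$O - Tmat[parent[idx], , drop = FALSE]
      loss <- mean(err^2)
      if (!is.finite(loss))
        stop(sprintf("training diverged (non-finite loss) at iteration %d", t))
      dO <- 2 * err / length(err)
      bk <- .eBackward(ew, ef$cache, dO)
      ggr <- .gBackward(gw, gf$cache, bk$dXd, g_spec)
      upE <- .adamStep(ew, bk$grads, e_state, sched$e_lr, t)
      ew <- upE$weights; e_state <- upE$state
      upG <- .adamStep(gw, ggr, g_state, sched$e_lr, t)
      gw <- upG$weights; g_state <- upG$state
      if (t %% sched$val_every == 0L || t == sched$iters) {
        hl <- holdLoss(gw, ew)
        log <- rbind(log, data.frame(iter = t, loss = loss, hold_loss = hl))
        if (hl < best$loss) best <- list(loss = hl, gw = gw, ew = ew, iter = t)
      }
    }
    new("NetworkBundle", g_spec = g_spec, d_spec = g$d_spec,
        e_spec = e$e_spec,
        weights = list(g = best$gw, d = g$d_weights, e = best$ew),
        training_log = log, irf_fingerprint = irfFingerprint(lib@irf),
        grid = decayGrid(lib@irf), tau_scale = tau_scale,
        stage = "combined")
  })
}

# ---- inference ----

.bundleCheckIRF <- function(bundle, irf, override) {
  if (!override && irfFingerprint(irf) != bundle@irf_fingerprint)
    stop(paste("IRF fingerprint mismatch: this bundle was trained for a",
               "different instrument response; retrain, or pass",
               "override_irf = TRUE"))
}

.bundleInferMatrix <- function(bundle, X, irf) {
  xi <- .irfInputRow(irf)
  Xi <- matrix(xi, nrow(X), length(xi), byrow = TRUE)
  Y <- .gForward(bundle@weights$g, X, Xi, bundle@g_spec)$Y
  O <- .eForward(bundle@weights$e, Y, Xi)$O
  ts <- bundle@tau_scale
  lifetimeParams(O[, 1], pmax(O[, 2] * ts, 0.01), pmax(O[, 3] * ts, 0.01))
}

#' Per-pixel lifetime inference with the trained bundle
#'
#' Strictly per-pixel: the restored decay and its parameters depend on
#' this pixel's histogram only. The input should be CoME-aligned when
#' the acquisition suffers onset drift; it is peak-normalized
#' internally.
#'
#' @param bundle a trained [NetworkBundle-class].
#' @param h a non-empty [DecayHistogram-class].
#' @param irf the [InstrumentResponse-class] of the data; must match the
#'   bundle's training IRF fingerprint.
#' @param override_irf set TRUE to bypass the fingerprint guard.
#' @return a [LifetimeParams-class] of length 1 (canonical order).
#' @export
inferPixel <- function(bundle, h, irf, override_irf = FALSE) {
  .bundleCheckIRF(bundle, irf, override_irf)
  cnt <- counts(h)
  if (sum(cnt) == 0) stop("empty pixel: no photons to infer from")
  X <- matrix(cnt / max(cnt), 1)
  .bundleInferMatrix(bundle, X, irf)
}

#' Whole-image lifetime inference with the trained bundle
#'
#' Applies [inferPixel()] to every pixel (vectorized in batches; results
#' are identical to pixel-by-pixel calls). Pixels with fewer than
#' `min_photons` photons are flagged failed and left NA.
#'
#' @param bundle a trained [NetworkBundle-class].
#' @param cube a [DecayCube-class] on the bundle's grid.
#' @param irf the matching [InstrumentResponse-class].
#' @param min_photons minimum photons per usable pixel.
#' @param override_irf bypass the IRF fingerprint guard.
#' @param chunk batch size for inference.
#' @return list of H x W matrices `tau_apparent`, `alpha1`, `tau1`,
#'   `tau2` and logical `failed`.
#' @export
inferImage <- function(bundle, cube, irf, min_photons = 1L,
                       override_irf = FALSE, chunk = 512L) {
  .bundleCheckIRF(bundle, irf, override_irf)
  if (nBins(cube) != nBins(bundle@grid))
    stop("grid mismatch between cube and bundle")
  d <- dim(cube)
  npix <- d[1] * d[2]
  X <- matrix(aperm(cube@counts, c(3, 1, 2)), nrow = npix, byrow = TRUE)
  tot <- rowSums(X)
  ok <- tot >= max(1L, min_photons)
  out <- list(tau_apparent = rep(NA_real_, npix),
              alpha1 = rep(NA_real_, npix), tau1 = rep(NA_real_, npix),
              tau2 = rep(NA_real_, npix), failed = !ok)
  idx <- which(ok)
  for (start in seq(1, length(idx), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, length(idx))]
    p <- .bundleInferMatrix(bundle, .peakNormRows(X[sel, , drop = FALSE]),
                            irf)
    out$tau_apparent[sel] <- apparentLifetime(p)
    out$alpha1[sel] <- alpha1(p)
    out$tau1[sel] <- tau1(p)
    out$tau2[sel] <- tau2(p)
  }
  lapply(out, function(v) matrix(v, d[1], d[2]))
}

#' Save / load a trained network bundle
#'
#' The bundle archive holds the three architecture specs, all weights,
#' the training log and the IRF fingerprint.
#'
#' @param bundle a [NetworkBundle-class].
#' @param path file path.
#' @return `loadBundle` returns the [NetworkBundle-class].
#' @export
saveBundle <- function(bundle, path) {
  saveRDS(list(g_spec = bundle@g_spec, d_spec = bundle@d_spec,
               e_spec = bundle@e_spec, weights = bundle@weights,
               training_log = bundle@training_log,
               irf_fingerprint = bundle@irf_fingerprint,
               n_bins = nBins(bundle@grid), period = period(bundle@grid),
               tau_scale = bundle@tau_scale, stage = bundle@stage),
          path)
  invisible(path)
}

#' @rdname saveBundle
#' @export
loadBundle <- function(path) {
  x <- readRDS(path)
  new("NetworkBundle", g_spec = x$g_spec, d_spec = x$d_spec,
      e_spec = x$e_spec, weights = x$weights,
      training_log = x$training_log,
      irf_fingerprint = x$irf_fingerprint,
      grid = histogramGrid(x$n_bins, x$period),
      tau_scale = x$tau_scale, stage = x$stage)
}
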