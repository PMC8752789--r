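# Minimal neural-network primitives (dense, circular conv1d, average
# pooling, activations) with hand-derived backpropagation, plus Adam and
# RMSprop optimizers. Everything operates on batch-major matrices: dense
# layers on B x features, convolutional stages on (B*L) x channels with
# row index r = b + (l-1) B, so circular shifts along the signal are row
# permutations and the inner products become single BLAS calls. The
# architectures in gan.R are small enough that this is fast on one CPU.
# Gradient correctness is checked against numeric differentiation in the
# test suite.

.nnSigmoid <- function(z) 1 / (1 + exp(-z))

# ---- dense ----
.denseF <- function(X, W, b) {
  Z <- X %*% W
  Z + rep(b, each = nrow(Z))
}
.denseB <- function(X, W, dZ) {
  list(dW = crossprod(X, dZ), db = colSums(dZ), dX = tcrossprod(dZ, W))
}

# ---- circular 1-d convolution on (B*L) x C matrices ----
# Precompute the K row permutations of the (b, l) layout for kernel
# taps; cached per (B, L, K).
.convPermCache <- new.env(parent = emptyenv())
.convPerms <- function(B, L, K) {
  key <- paste(B, L, K)
  hit <- .convPermCache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- K %/% 2L
  perms <- lapply(seq_len(K), function(k) {
    lsrc <- ((seq_len(L) - 1L + k - 1L - pad) %% L) + 1L
    as.vector(outer(seq_len(B), (lsrc - 1L) * B, "+"))
  })
  .convPermCache[[key]] <- perms
  perms
}

# Single flat gather index for the (B*L) x (K*Cin) im2col matrix.
.convGatherCache <- new.env(parent = emptyenv())
.convGather <- function(B, L, K, Cin) {
  key <- paste(B, L, K, Cin)
  hit <- .convGatherCache[[key]]
  if (!is.null(hit)) return(hit)
  perms <- .convPerms(B, L, K)
  BL <- B * L
  idx <- integer(BL * K * Cin)
  pos <- 0L
  # column order k-fastest, matching matrix(W, K*Cin, Cout) row order
  for (c in seq_len(Cin)) for (k in seq_len(K)) {
    idx[pos + seq_len(BL)] <- perms[[k]] + (c - 1L) * BL
    pos <- pos + BL
  }
  .convGatherCache[[key]] <- idx
  idx
}

# X: (B*L) x Cin; W: K x Cin x Cout; returns (B*L) x Cout.
.convF <- function(X, W, b, B, L) {
  K <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  Xcol <- matrix(X[.convGather(B, L, K, Cin)], B * L, K * Cin)
  Wmat <- matrix(W, K * Cin, Cout)   # row k + (c-1)*K  <- W[k, c, o]
  Z <- Xcol %*% Wmat
  list(out = Z + rep(b, each = B * L), Xcol = Xcol)
}

.convB <- function(cache, W, dZ, B, L) {
  K <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  perms <- .convPerms(B, L, K)
  Wmat <- matrix(W, K * Cin, Cout)
  dW <- array(crossprod(cache$Xcol, dZ), dim(W))
  db <- colSums(dZ)
  dXcol <- tcrossprod(dZ, Wmat)
  dX <- matrix(0, B * L, Cin)
  for (k in seq_len(K)) {
    p <- perms[[k]]
    dX[p, ] <- dX[p, , drop = FALSE] +
      dXcol[, k + (seq_len(Cin) - 1L) * K, drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

# ---- average pooling (width = stride) on (B*L) x C matrices ----
.poolRowsCache <- new.env(parent = emptyenv())
.poolRows <- function(B, L, width) {
  key <- paste(B, L, width)
  hit <- .poolRowsCache[[key]]
  if (!is.null(hit)) return(hit)
  L2 <- L %/% width
  sel <- lapply(seq_len(width), function(i) {
    lsrc <- (seq_len(L2) - 1L) * width + i
    as.vector(outer(seq_len(B), (lsrc - 1L) * B, "+"))
  })
  .poolRowsCache[[key]] <- sel
  sel
}

.poolF <- function(X, B, L, width = 4L) {
  sel <- .poolRows(B, L, width)
  out <- X[sel[[1]], , drop = FALSE]
  for (i in 2:width) out <- out + X[sel[[i]], , drop = FALSE]
  out / width
}

.poolB <- function(dOut, B, L, width = 4L) {
  sel <- .poolRows(B, L, width)
  dX <- matrix(0, B * L, ncol(dOut))
  g <- dOut / width
  for (i in seq_len(width)) dX[sel[[i]], ] <- g
  dX
}

# ---- weight initialization ----
.initMat <- function(nin, nout, gain = sqrt(2)) {
  matrix(stats::rnorm(nin * nout, sd = gain / sqrt(nin)), nin, nout)
}
.initConv <- function(K, Cin, Cout, gain = sqrt(2)) {
  array(stats::rnorm(K * Cin * Cout, sd = gain / sqrt(K * Cin)),
        c(K, Cin, Cout))
}

# ---- optimizers (operate on flat named lists of arrays) ----
.optInit <- function(weights) {
  lapply(weights, function(w) list(m = w * 0, v = w * 0))
}

.adamStep <- function(weights, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(weights)) {
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * grads[[nm]]
    st$v <- beta2 * st$v + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(weights = weights, state = state)
}

.rmspropStep <- function(weights, grads, state, lr, rho = 0.9,
                         eps = 1e-8) {
  for (nm in names(weights)) {
    st <- state[[nm]]
    st$v <- rho * st$v + (1 - rho) * grads[[nm]]^2
    weights[[nm]] <- weights[[nm]] - lr * grads[[nm]] / (sqrt(st$v) + eps)
    state[[nm]] <- st
  }
  list(weights = weights, state = state)
}

.clipWeights <- function(weights, c) {
  lapply(weights, function(w) pmin(pmax(w, -c), c))
}
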