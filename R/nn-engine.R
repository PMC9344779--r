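# Minimal CNN engine used by the patch classifier. Pure R: convolutions are
# im2col gathers followed by BLAS GEMM, so the heavy lifting happens inside
# matrix multiplication. Data layout everywhere: arrays (H, W, C, N) with
# the sample index last; weight matrices for 3x3 same-padding convolutions
# are (9 * Cin) x Cout with im2col column order (di, dj) fastest, channel
# slowest.

padHW <- function(X) {
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  Xp[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- X
  Xp
}

# Kernel offsets k = 1..9 enumerate (di, dj) with di fastest; the weight
# matrix rows are (k, c) with k fastest, so offset k of channel c sits in
# row k + 9 * (c - 1).
.convOffsets <- cbind(di = rep(0:2, times = 3), dj = rep(0:2, each = 3))

# Activations flow through conv/pool stages in (H, W, N, C) layout — with
# the sample index *third* — so that a shifted spatial block flattens
# straight into a (pixel * image) x channel matrix with no transposition.
# The public nnForward() entry point accepts the natural (H, W, C, N)
# layout and permutes once.

# One shifted block of a padded (H+2, W+2, N, C) activation array,
# flattened to rows (pixel, image) x channel.
shiftBlock <- function(Xp, di, dj, H, W) {
  B <- Xp[(1L + di):(H + di), (1L + dj):(W + dj), , , drop = FALSE]
  d <- dim(B)
  dim(B) <- c(H * W * d[3], d[4])
  B
}

# 3x3 same-padding convolution, computed as nine shifted-block GEMMs
# (contiguous copies instead of scattered im2col gathers). With
# `keepBlocks` the shifted blocks are retained for the backward pass.
convForward <- function(X, Wm, b, keepBlocks = FALSE) {
  d <- dim(X)                      # (H, W, N, C)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  nF <- length(b)
  Xp <- padHW(X)
  Y <- matrix(rep(b, each = H * W * N), H * W * N, nF)
  blocks <- if (keepBlocks) vector("list", 9L)
  for (k in 1:9) {
    Bk <- shiftBlock(Xp, .convOffsets[k, 1], .convOffsets[k, 2], H, W)
    if (keepBlocks) blocks[[k]] <- Bk
    Wk <- Wm[seq.int(k, by = 9L, length.out = C), , drop = FALSE]
    Y <- Y + Bk %*% Wk
  }
  dim(Y) <- c(H, W, N, nF)
  list(Y = Y, blocks = blocks, inDim = d)
}

# Backward pass. The input gradient is skipped (NULL) for the first layer
# of a network via `needInputGrad`.
convBackward <- function(dY, cache, Wm, needInputGrad = TRUE) {
  d <- cache$inDim                 # (H, W, N, C)
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  nF <- dim(dY)[4]
  dYm <- dY
  dim(dYm) <- c(H * W * N, nF)
  db <- colSums(dYm)
  dW <- matrix(0, 9L * C, nF)
  dXp <- if (needInputGrad) array(0, c(H + 2L, W + 2L, N, C))
  for (k in 1:9) {
    di <- .convOffsets[k, 1]; dj <- .convOffsets[k, 2]
    dW[seq.int(k, by = 9L, length.out = C), ] <- crossprod(cache$blocks[[k]], dYm)
    if (needInputGrad) {
      G <- dYm %*% t(Wm[seq.int(k, by = 9L, length.out = C), , drop = FALSE])
      dim(G) <- c(H, W, N, C)
      rows <- (1L + di):(H + di); cols <- (1L + dj):(W + dj)
      dXp[rows, cols, , ] <- dXp[rows, cols, , ] + G
    }
  }
  dX <- if (needInputGrad) dXp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# 2x2 max pooling, stride 2 (even H, W assumed). Ties go to the first of
# the four positions in (top-left, bottom-left, top-right, bottom-right)
# order.
poolForward <- function(X) {
  d <- dim(X)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  a11 <- X[i1, j1, , , drop = FALSE]
  a21 <- X[i1 + 1L, j1, , , drop = FALSE]
  a12 <- X[i1, j1 + 1L, , , drop = FALSE]
  a22 <- X[i1 + 1L, j1 + 1L, , , drop = FALSE]
  Y <- pmax(a11, a21, a12, a22)
  m11 <- a11 == Y
  m21 <- (a21 == Y) & !m11
  m12 <- (a12 == Y) & !(m11 | m21)
  m22 <- !(m11 | m21 | m12)
  list(Y = Y, masks = list(m11, m21, m12, m22), inDim = d)
}

poolBackward <- function(dY, cache) {
  d <- cache$inDim
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dX <- array(0, d)
  m <- cache$masks
  dX[i1, j1, , ] <- dY * m[[1]]
  dX[i1 + 1L, j1, , ] <- dY * m[[2]]
  dX[i1, j1 + 1L, , ] <- dY * m[[3]]
  dX[i1 + 1L, j1 + 1L, , ] <- dY * m[[4]]
  dX
}

activationForward <- function(X, kind) {
  if (kind == "ReLU") {
    Y <- X; Y[Y < 0] <- 0
    list(Y = Y, cache = X > 0)
  } else {
    S <- 1 / (1 + exp(-X))
    list(Y = S, cache = S)
  }
}

activationBackward <- function(dY, cache, kind) {
  if (kind == "ReLU") dY * cache else dY * cache * (1 - cache)
}

# Inverted dropout: activations are scaled at train time so evaluation is
# the identity.
dropoutForward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, cache = NULL))
  mask <- (stats::runif(length(X)) >= rate) / (1 - rate)
  dim(mask) <- dim(X)
  list(Y = X * mask, cache = mask)
}

# Affine input is either a (K x N) matrix (between affine layers) or a
# (H, W, N, C) conv-stage array, which is permuted so each column holds
# one sample's flattened features.
affineForward <- function(X, Wd, b) {
  d <- dim(X)
  if (length(d) == 4L) {
    N <- d[3]
    Xm <- matrix(aperm(X, c(1, 2, 4, 3)), ncol = N)
  } else {
    N <- d[2]
    Xm <- X
  }
  Z <- Wd %*% Xm + rep(b, times = N)
  list(Y = Z, Xm = Xm, inDim = d)
}

affineBackward <- function(dZ, cache, Wd) {
  d <- cache$inDim
  dXm <- crossprod(Wd, dZ)
  dX <- if (length(d) == 4L) {
    aperm(array(dXm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  } else {
    matrix(dXm, d[1], d[2])
  }
  list(dX = dX, dW = tcrossprod(dZ, cache$Xm), db = rowSums(dZ))
}

# Numerically stable softmax over a (K x N) score matrix.
softmaxProbs <- function(Z) {
  K <- nrow(Z)
  Zs <- Z - rep(apply(Z, 2, max), each = K)
  E <- exp(Zs)
  E / rep(colSums(E), each = K)
}

# Categorical cross-entropy of probabilities P (K x N) against class
# indices y; gradient is with respect to the pre-softmax scores.
crossEntropy <- function(P, y) {
  N <- ncol(P)
  -mean(log(P[cbind(y, seq_len(N))] + 1e-12))
}

softmaxBackward <- function(P, y) {
  N <- ncol(P)
  dZ <- P
  dZ[cbind(y, seq_len(N))] <- dZ[cbind(y, seq_len(N))] - 1
  dZ / N
}

# ---- whole-network passes --------------------------------------------------

# Forward through a layer list. `X` is (H, W, C, N); returns class
# probabilities (K x N) and, when `keepCaches`, everything the backward
# pass needs.
nnForward <- function(layers, X, activation, training = FALSE, keepCaches = FALSE) {
  caches <- if (keepCaches) vector("list", length(layers)) else NULL
  cur <- aperm(X, c(1, 2, 4, 3))   # internal conv layout (H, W, N, C)
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    if (lay$type == "conv") {
      r <- convForward(cur, lay$W, lay$b, keepBlocks = keepCaches)
      if (keepCaches) caches[[li]] <- list(blocks = r$blocks, inDim = r$inDim)
      cur <- r$Y
    } else if (lay$type == "act") {
      r <- activationForward(cur, activation)
      if (keepCaches) caches[[li]] <- r$cache
      cur <- r$Y
    } else if (lay$type == "pool") {
      r <- poolForward(cur)
      if (keepCaches) caches[[li]] <- r[c("masks", "inDim")]
      cur <- r$Y
    } else if (lay$type == "dropout") {
      r <- dropoutForward(cur, lay$rate, training)
      if (keepCaches) caches[[li]] <- r$cache
      cur <- r$Y
    } else if (lay$type == "affine") {
      r <- affineForward(cur, lay$W, lay$b)
      if (keepCaches) caches[[li]] <- r[c("Xm", "inDim")]
      cur <- r$Y
    } else if (lay$type == "softmax") {
      cur <- softmaxProbs(cur)
    } else stop("unknown layer type: ", lay$type)
  }
  list(P = cur, caches = caches)
}

# Backward pass; returns per-layer gradient list (NULL for parameter-free
# layers). `fw` is the value of nnForward(..., keepCaches = TRUE).
nnBackward <- function(layers, fw, y, activation) {
  grads <- vector("list", length(layers))
  d <- NULL
  for (li in rev(seq_along(layers))) {
    lay <- layers[[li]]
    if (lay$type == "softmax") {
      d <- softmaxBackward(fw$P, y)
    } else if (lay$type == "affine") {
      r <- affineBackward(d, fw$caches[[li]], lay$W)
      grads[[li]] <- list(dW = r$dW, db = r$db)
      d <- r$dX
    } else if (lay$type == "dropout") {
      if (!is.null(fw$caches[[li]])) d <- d * fw$caches[[li]]
    } else if (lay$type == "pool") {
      d <- poolBackward(d, fw$caches[[li]])
    } else if (lay$type == "act") {
      d <- activationBackward(d, fw$caches[[li]], activation)
    } else if (lay$type == "conv") {
      r <- convBackward(d, fw$caches[[li]], lay$W, needInputGrad = li > 1L)
      grads[[li]] <- list(dW = r$dW, db = r$db)
      d <- r$dX
    }
  }
  grads
}

# ---- ADAM ------------------------------------------------------------------

adamInit <- function(layers) {
  lapply(layers, function(lay) {
    if (!is.null(lay$W)) list(mW = lay$W * 0, vW = lay$W * 0,
                              mb = lay$b * 0, vb = lay$b * 0)
  })
}

adamStep <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    s <- state[[li]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[li]]$W <- layers[[li]]$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    layers[[li]]$b <- layers[[li]]$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[li]] <- s
  }
  list(layers = layers, state = state)
}
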