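# Internal CNN machinery.
#
# A sample is a column vector over (h, w, c) in column-major order:
# index(h, w, c) = h + (w-1)*H + (c-1)*H*W.  A batch is a D x B matrix.
# Convolutions run as im2col gathers followed by one BLAS gemm; the gather
# plans (integer index vectors) depend only on layer shapes and are built
# once per model.  Large batches are processed in sample chunks to bound
# the size of the gathered column matrix.

.CHUNK_ELTS <- 2e7

# im2col plan for one convolution layer.
# Padded input has an extra phantom zero cell at index Dp + 1 so "same"
# padding needs no special-casing in the gather.
.convPlan <- function(H, W, C, k, stride, padding) {
  if (padding == "same") {
    padTotal <- k - 1L
    padBeg <- padTotal %/% 2L
    Hp <- H + padTotal; Wp <- W + padTotal
    Hout <- (Hp - k) %/% stride + 1L
    Wout <- (Wp - k) %/% stride + 1L
  } else {
    padBeg <- 0L
    Hp <- H; Wp <- W
    Hout <- (H - k) %/% stride + 1L
    Wout <- (W - k) %/% stride + 1L
    if (Hout < 1L || Wout < 1L)
      stop("input ", H, " x ", W, " smaller than the ", k, " x ", k,
           " receptive field under valid padding")
  }
  Dp <- Hp * Wp * C
  # gather index over (kh, kw, c) x (ho, wo): kernel offsets fastest
  kh <- rep.int(seq_len(k), k * C)
  kw <- rep.int(rep(seq_len(k), each = k), C)
  kc <- rep(seq_len(C), each = k * k)
  off <- (kh - 1L) + (kw - 1L) * Hp + (kc - 1L) * Hp * Wp       # KKC
  h0 <- (rep.int(seq_len(Hout), Wout) - 1L) * stride            # P
  w0 <- (rep(seq_len(Wout), each = Hout) - 1L) * stride
  base <- 1L + h0 + w0 * Hp
  idx <- as.integer(outer(off, base, "+"))                      # KKC * P
  # map original cells into the padded frame (identity when unpadded)
  if (padding == "same") {
    h <- rep.int(seq_len(H), W * C)
    w <- rep.int(rep(seq_len(W), each = H), C)
    cc <- rep(seq_len(C), each = H * W)
    origPos <- (h + padBeg) + (w + padBeg - 1L) * Hp + (cc - 1L) * Hp * Wp
  } else {
    origPos <- seq_len(Dp)
  }
  list(H = H, W = W, C = C, k = k, stride = stride, padding = padding,
       Hp = Hp, Wp = Wp, Dp = Dp, Hout = Hout, Wout = Wout,
       KKC = k * k * C, P = Hout * Wout, idx = idx,
       origPos = as.integer(origPos))
}

# X: (H*W*C) x B.  Returns (Hout*Wout*F) x B.
.convForward <- function(X, Wt, b, plan) {
  .convForwardCpp(X, Wt, b, plan$idx, plan$origPos, plan$Dp, plan$P)
}

# Pure-R reference path for the same computation; retained as the
# cross-check oracle for the compiled kernels.
.convForwardR <- function(X, Wt, b, plan) {
  B <- ncol(X)
  F <- nrow(Wt)
  out <- matrix(0, plan$P * F, B)
  chunk <- max(1L, as.integer(.CHUNK_ELTS / (plan$KKC * plan$P)))
  pad <- plan$padding == "same"
  for (s in seq(1L, B, by = chunk)) {
    e <- min(B, s + chunk - 1L)
    nb <- e - s + 1L
    if (pad) {
      Xp <- matrix(0, plan$Dp + 1L, nb)
      Xp[plan$origPos, ] <- X[, s:e]
    } else {
      Xp <- if (nb == B) X else X[, s:e, drop = FALSE]
    }
    Cols <- Xp[plan$idx, , drop = FALSE]
    dim(Cols) <- c(plan$KKC, plan$P * nb)
    Z <- Wt %*% Cols + b
    dim(Z) <- c(F, plan$P, nb)
    out[, s:e] <- matrix(aperm(Z, c(2L, 1L, 3L)), plan$P * F, nb)
  }
  out
}

# dOut: (P*F) x B.  Returns gradients and (optionally) dX.
.convBackward <- function(X, Wt, plan, dOut, needDx = TRUE) {
  out <- .convBackwardCpp(X, Wt, plan$idx, plan$origPos, plan$Dp, plan$P,
                          dOut, needDx)
  out$db <- as.numeric(out$db)
  if (!needDx) out$dX <- NULL
  out
}

.convBackwardR <- function(X, Wt, plan, dOut, needDx = TRUE) {
  B <- ncol(X)
  F <- nrow(Wt)
  dW <- matrix(0, F, plan$KKC)
  db <- numeric(F)
  dX <- if (needDx) matrix(0, nrow(X), B) else NULL
  chunk <- max(1L, as.integer(.CHUNK_ELTS / (plan$KKC * plan$P)))
  pad <- plan$padding == "same"
  for (s in seq(1L, B, by = chunk)) {
    e <- min(B, s + chunk - 1L)
    nb <- e - s + 1L
    if (pad) {
      Xp <- matrix(0, plan$Dp + 1L, nb)
      Xp[plan$origPos, ] <- X[, s:e]
    } else {
      Xp <- if (nb == B) X else X[, s:e, drop = FALSE]
    }
    Cols <- Xp[plan$idx, , drop = FALSE]
    dim(Cols) <- c(plan$KKC, plan$P * nb)
    dZ <- array(dOut[, s:e], c(plan$P, F, nb))
    dZ <- matrix(aperm(dZ, c(2L, 1L, 3L)), F, plan$P * nb)
    dW <- dW + tcrossprod(dZ, Cols)
    db <- db + rowSums(dZ)
    if (needDx) {
      dCols <- crossprod(Wt, dZ)
      dim(dCols) <- c(plan$KKC * plan$P, nb)
      acc <- rowsum(dCols, plan$idx)
      dXp <- matrix(0, plan$Dp + 1L, nb)
      dXp[as.integer(rownames(acc)), ] <- acc
      dX[, s:e] <- dXp[plan$origPos, , drop = FALSE]
    }
  }
  list(dW = dW, db = db, dX = dX)
}

.BN_EPS <- 1e-5

# Dense layer with batch normalisation and ReLU: z = W x + b, then BN over
# the batch, then ReLU.  Layer state: W, b, gamma, beta, runMean, runVar.
.denseBnForward <- function(X, layer, training, momentum) {
  Z <- layer$W %*% X + layer$b
  if (training) {
    mu <- rowMeans(Z)
    v <- rowMeans((Z - mu)^2)
    layer$runMean <- momentum * layer$runMean + (1 - momentum) * mu
    layer$runVar <- momentum * layer$runVar + (1 - momentum) * v
  } else {
    mu <- layer$runMean
    v <- layer$runVar
  }
  inv <- 1 / sqrt(v + .BN_EPS)
  Zhat <- (Z - mu) * inv
  A <- layer$gamma * Zhat + layer$beta
  out <- pmax(A, 0)
  list(out = out, layer = layer,
       cache = list(X = X, Z = Z, Zhat = Zhat, inv = inv, mask = A > 0))
}

.denseBnBackward <- function(layer, cache, dOut) {
  dA <- dOut * cache$mask
  dgamma <- rowSums(dA * cache$Zhat)
  dbeta <- rowSums(dA)
  B <- ncol(dA)
  dZhat <- dA * layer$gamma
  # batch-norm backward (population batch statistics)
  sum1 <- rowSums(dZhat)
  sum2 <- rowSums(dZhat * cache$Zhat)
  dZ <- (dZhat - sum1 / B - cache$Zhat * sum2 / B) * cache$inv
  dW <- tcrossprod(dZ, cache$X)
  db <- rowSums(dZ)
  dX <- crossprod(layer$W, dZ)
  list(dW = dW, db = db, dgamma = dgamma, dbeta = dbeta, dX = dX)
}

# Gradient of the training objective with respect to the predictions.
# composite: alpha * (1 - R) + (1 - alpha) * RMSE; the R term is dropped
# (pure RMSE) when the batch predictions are degenerate (zero variance).
.lossGradient <- function(pred, obs, alpha, lossMode) {
  n <- length(pred)
  resid <- pred - obs
  rmseVal <- sqrt(mean(resid^2))
  dRmse <- if (rmseVal > 0) resid / (n * rmseVal) else numeric(n)
  if (lossMode == "rmse") {
    return(list(loss = rmseVal, grad = dRmse))
  }
  a <- pred - mean(pred)
  bb <- obs - mean(obs)
  Sa <- sqrt(sum(a^2)); Sb <- sqrt(sum(bb^2))
  if (Sa <= 1e-12 || Sb <= 1e-12) {      # degenerate batch: RMSE term only
    return(list(loss = alpha + (1 - alpha) * rmseVal,
                grad = (1 - alpha) * dRmse))
  }
  R <- sum(a * bb) / (Sa * Sb)
  dR <- bb / (Sa * Sb) - R * a / Sa^2
  list(loss = alpha * (1 - R) + (1 - alpha) * rmseVal,
       grad = -alpha * dR + (1 - alpha) * dRmse)
}
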