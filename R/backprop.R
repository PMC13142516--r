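# Manual reverse-mode gradients for the cross-attention predictor, and the
# Adam update used by the trainer. Gradients are verified against central
# finite differences in the test suite.

# Binary cross-entropy (mean over residues) with probability clamping.
bceCore <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Loss and gradients for one (query, partner, label) triple.
# `dropout` enables the MLP dropout mask (training mode); the mask is drawn
# from the current RNG stream, so callers seed per-step for determinism.
pairGradients <- function(EA, EB, y, params, config = params$config,
                          dropout = TRUE, posWeight = 1) {
  X <- embValues(EA); Y <- embValues(EB)
  LA <- nrow(X); LB <- nrow(Y)
  d <- config@embedDim; H <- config@numHeads; dh <- config@headDim
  s <- attnScale(config)

  fw <- forwardPair(EA, EB, params, config, keep = TRUE, dropout = dropout)
  loss <- if (posWeight == 1) bceCore(fw$p, y)
          else weightedBce(fw$p, y, posWeight)

  g <- list()
  # sigmoid + BCE: d loss / d logit = (p - y) / L_A (w = 1), generally
  # ((1 - y) p - w y (1 - p)) / L_A
  du <- ((1 - y) * fw$p - posWeight * y * (1 - fw$p)) / LA
  g$mlpW2 <- t(fw$H1) %*% du
  g$mlpB2 <- sum(du)
  dH1 <- outer(du, drop(params$mlpW2))
  if (!is.null(fw$mask)) dH1 <- dH1 * fw$mask
  dPre1 <- dH1 * (fw$pre1 > 0)
  g$mlpW1 <- t(fw$ln$out) %*% dPre1
  g$mlpB1 <- colSums(dPre1)
  dN <- dPre1 %*% t(params$mlpW1)

  # LayerNorm backward (per row, mean over the d features)
  nhat <- fw$ln$nhat
  g$lnGain <- colSums(dN * nhat)
  g$lnBias <- colSums(dN)
  dnh <- sweep(dN, 2L, params$lnGain, `*`)
  rm1 <- rowMeans(dnh)
  rm2 <- rowMeans(dnh * nhat)
  dZ <- (dnh - rm1 - nhat * rm2) / fw$ln$sd

  Q <- X %*% params$Wq + rep(params$bq, each = LA)
  K <- Y %*% params$Wk + rep(params$bk, each = LB)
  V <- Y %*% params$Wv + rep(params$bv, each = LB)

  # output projection (residual, when enabled, passes dZ through unchanged
  # to X, which is constant input — no parameter gradient there)
  O <- matrix(0, LA, d)
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    O[, idx] <- fw$ca$attention[[h]] %*% V[, idx, drop = FALSE]
  }
  g$Wo <- t(O) %*% dZ
  g$bo <- colSums(dZ)
  dO <- dZ %*% t(params$Wo)
  dQ <- matrix(0, LA, d); dK <- matrix(0, LB, d); dV <- matrix(0, LB, d)
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- fw$ca$attention[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dV[, idx] <- t(A) %*% dOh
    dA <- dOh %*% t(V[, idx, drop = FALSE])
    dS <- A * (dA - rowSums(dA * A))    # softmax Jacobian, row-wise
    dQ[, idx] <- dS %*% K[, idx, drop = FALSE] / s
    dK[, idx] <- t(dS) %*% Q[, idx, drop = FALSE] / s
  }
  g$Wq <- t(X) %*% dQ; g$bq <- colSums(dQ)
  g$Wk <- t(Y) %*% dK; g$bk <- colSums(dK)
  g$Wv <- t(Y) %*% dV; g$bv <- colSums(dV)

  list(loss = loss, grads = g)
}

# ---------------------------------------------------------------------------
# Adam
# ---------------------------------------------------------------------------

adamInit <- function(params) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in paramNames()) {
    st$m[[nm]] <- params[[nm]] * 0
    st$v[[nm]] <- params[[nm]] * 0
  }
  st
}

adamStep <- function(params, grads, state, lr = 1e-3,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in paramNames()) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
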