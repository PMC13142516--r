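# Shared fixtures: tiny configurations, random embeddings, and an
# independent dense-loop implementation of the forward pass used as the
# arithmetic oracle for the vectorised model code.

paramNamesForTest <- function() crossPPI:::paramNames()
countInstantiatedForTest <- function(p) crossPPI:::countInstantiated(p)

tinyConfig <- function(d = 8L, heads = 2L, mlpHidden = d, dropout = 0) {
  modelConfig(embedDim = d, numHeads = heads, mlpHidden = mlpHidden,
              dropoutRate = dropout)
}

randomEmbedding <- function(L, d, seed, id = "seq") {
  set.seed(seed)
  embeddingMatrix(id, matrix(rnorm(L * d), L, d), "synthetic")
}

# Dense, loop-based re-implementation of the forward pass: scalar loops
# only, no reuse of package internals beyond the parameter list layout.
denseForwardOracle <- function(X, Y, params, config) {
  d <- embedDim(config); H <- numHeads(config); dh <- headDim(config)
  s <- if (config@attentionScaleMode == "per_head_sqrt") sqrt(dh) else sqrt(d)
  LA <- nrow(X); LB <- nrow(Y)
  lin <- function(M, W, b) {
    out <- matrix(0, nrow(M), ncol(W))
    for (i in seq_len(nrow(M)))
      for (j in seq_len(ncol(W))) {
        acc <- b[j]
        for (k in seq_len(ncol(M))) acc <- acc + M[i, k] * W[k, j]
        out[i, j] <- acc
      }
    out
  }
  Q <- lin(X, params$Wq, params$bq)
  K <- lin(Y, params$Wk, params$bk)
  V <- lin(Y, params$Wv, params$bv)
  O <- matrix(0, LA, d)
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    for (i in seq_len(LA)) {
      logits <- numeric(LB)
      for (j in seq_len(LB))
        logits[j] <- sum(Q[i, idx] * K[j, idx]) / s
      w <- exp(logits - max(logits))
      w <- w / sum(w)
      for (k in idx)
        O[i, k] <- sum(w * V[, k])
    }
  }
  Z <- lin(O, params$Wo, params$bo)
  if (config@useResidual) Z <- Z + X
  P <- numeric(LA)
  for (i in seq_len(LA)) {
    mu <- mean(Z[i, ])
    va <- mean((Z[i, ] - mu)^2)
    nh <- (Z[i, ] - mu) / sqrt(va + 1e-5)
    nrm <- nh * params$lnGain + params$lnBias
    h1 <- numeric(config@mlpHidden)
    for (j in seq_len(config@mlpHidden))
      h1[j] <- max(0, sum(nrm * params$mlpW1[, j]) + params$mlpB1[j])
    u <- sum(h1 * params$mlpW2[, 1L]) + params$mlpB2
    P[i] <- 1 / (1 + exp(-u))
  }
  P
}

# Brute-force AUROC: fraction of (positive, negative) pairs correctly
# ordered, ties counting one half.
pairOrderAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos)
    for (n in neg)
      tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Independent reimplementation of the planted-label rule by direct string
# matching, used to verify generator ground truth.
matchLabelsOracle <- function(query, partner, rule) {
  lab <- integer(nchar(query))
  for (mp in rule$motifPairs) {
    if (!grepl(mp[2L], partner, fixed = TRUE)) next
    start <- 1L
    repeat {
      hit <- regexpr(mp[1L], substr(query, start, nchar(query)), fixed = TRUE)
      if (hit == -1L) break
      at <- start + hit - 1L
      lab[at:(at + nchar(mp[1L]) - 1L)] <- 1L
      start <- at + 1L
    }
  }
  lab
}

# Small planted-rule library used across training-related tests (four
# self-complementary couples, as in the generator's default library).
testRule <- function()
  plantedRule(motifPairs = lapply(c("HWY", "DKE", "CMF", "RQN"),
                                  function(m) c(m, m)))

# Embed a generated pair list with the synthetic backend.
embedPairs <- function(pairs, d = 32L, seed = 1L) {
  emb <- embedderSpec("synthetic", embedDim = d, seed = seed)
  lapply(pairs, function(pr)
    list(EA = embedSequence(pr$query, emb, pr$queryId),
         EB = embedSequence(pr$partner, emb, pr$partnerId),
         labels = pr$labels, partner = pr$partner))
}
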