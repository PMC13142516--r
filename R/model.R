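# Partner-aware cross-attention model: parameter container, forward pass,
# parameter accounting and weight inspection.
#
# The architecture: per-residue embeddings of a query A and a partner B are
# projected to queries/keys/values; multi-head attention of A over B yields a
# partner-conditioned representation of every query residue, which is passed
# through an output projection, LayerNorm, and a two-layer MLP (linear, ReLU,
# dropout) ending in a sigmoid, giving one interaction probability per query
# residue. Query information reaches the output only through the attention
# weights (no residual by default), so a prediction is partner-conditioned by
# construction.

#' Initialise model parameters
#'
#' Creates a full parameter set for a given configuration using scaled
#' uniform fan-in initialisation (each weight uniform on
#' `+/- 1/sqrt(fan_in)`), zero biases except the output bias which is set to
#' `outputBiasInit`. Deterministic for a fixed seed; the caller's RNG state
#' is left untouched.
#'
#' `qkMatchInit` optionally adds a scaled identity matrix to the query and
#' key projections, so that attention starts out as a content-similarity
#' matcher (a query residue initially attends most to partner residues with
#' near-identical embeddings). This seeds the partner-matching circuit the
#' architecture is meant to learn and substantially accelerates small-scale
#' training; at 0 (the default) the initialisation is plain scaled-uniform.
#'
#' @param config A [ModelConfig-class].
#' @param seed Integer seed.
#' @param qkMatchInit Non-negative scale of the identity component added to
#'   the query and key projections (default 0).
#' @return A `ModelParams` list with elements `Wq, bq, Wk, bk, Wv, bv, Wo,
#'   bo, lnGain, lnBias, mlpW1, mlpB1, mlpW2, mlpB2`, the `config`, and a
#'   `trained` flag.
#' @examples
#' p <- initModel(modelConfig(embedDim = 8, numHeads = 2), seed = 1)
#' dim(p$Wq)
#' @export
initModel <- function(config, seed = 0L, qkMatchInit = 0) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  d <- config@embedDim; m <- config@mlpHidden
  withSeed(seed, {
    u <- function(nr, nc) {
      lim <- 1 / sqrt(nr)
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    }
    params <- list(
      Wq = u(d, d) + qkMatchInit * diag(d), bq = numeric(d),
      Wk = u(d, d) + qkMatchInit * diag(d), bk = numeric(d),
      Wv = u(d, d), bv = numeric(d),
      Wo = u(d, d), bo = numeric(d),
      lnGain = rep(1, d), lnBias = numeric(d),
      mlpW1 = u(d, m), mlpB1 = numeric(m),
      mlpW2 = u(m, 1L), mlpB2 = config@outputBiasInit,
      config = config, trained = FALSE
    )
    class(params) <- "ModelParams"
    params
  })
}

# Names of the trainable tensors within a ModelParams list, in a fixed order.
paramNames <- function() c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                           "lnGain", "lnBias", "mlpW1", "mlpB1", "mlpW2", "mlpB2")

#' @export
print.ModelParams <- function(x, ...) {
  cfg <- x$config
  cat("ModelParams: d =", cfg@embedDim, "| heads =", cfg@numHeads,
      "|", countParameters(cfg)["total"], "trainable values |",
      if (isTRUE(x$trained)) "trained" else "untrained", "\n")
  invisible(x)
}

checkDims <- function(EA, EB, config) {
  d <- config@embedDim
  if (ncol(embValues(EA)) != d || ncol(embValues(EB)) != d)
    stop("shape error: embedding dimension (", ncol(embValues(EA)), "/",
         ncol(embValues(EB)), ") does not match config embedDim ", d,
         call. = FALSE)
  invisible(TRUE)
}

attnScale <- function(config) {
  if (config@attentionScaleMode == "per_head_sqrt") sqrt(config@headDim)
  else sqrt(config@embedDim)
}

#' Multi-head cross-attention of a query over a partner
#'
#' Computes scaled dot-product attention where queries come from sequence A
#' and keys/values from sequence B. Per head, attention logits are
#' `Q_h K_h' / s` with `s` set by the configuration's scale mode; rows are
#' softmax-normalised (with max subtraction) over the partner positions so
#' each query residue distributes unit mass over the partner. The per-head
#' contexts `A_h V_h` are concatenated and passed through the output
#' projection.
#'
#' @param EA,EB [EmbeddingMatrix-class] objects for the query (A) and
#'   partner (B); both must match the configured embedding dimension.
#' @param params `ModelParams` from [initModel()].
#' @param config A [ModelConfig-class].
#' @return List with `attended` (L_A x d matrix, after the output
#'   projection) and `attention` (list of per-head L_A x L_B matrices).
#' @export
crossAttention <- function(EA, EB, params, config = params$config) {
  checkDims(EA, EB, config)
  X <- embValues(EA); Y <- embValues(EB)
  d <- config@embedDim; H <- config@numHeads; dh <- config@headDim
  s <- attnScale(config)
  Q <- X %*% params$Wq + rep(params$bq, each = nrow(X))
  K <- Y %*% params$Wk + rep(params$bk, each = nrow(Y))
  V <- Y %*% params$Wv + rep(params$bv, each = nrow(Y))
  O <- matrix(0, nrow(X), d)
  attn <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- softmaxRows(Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / s)
    attn[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  attended <- O %*% params$Wo + rep(params$bo, each = nrow(X))
  if (config@useResidual) attended <- attended + X
  list(attended = attended, attention = attn)
}

# Row-wise LayerNorm; returns normalised matrix plus the per-row statistics
# needed for backpropagation.
layerNormRows <- function(Z, gain, bias, eps = 1e-5) {
  mu <- rowMeans(Z)
  zc <- Z - mu
  va <- rowMeans(zc^2)
  sd <- sqrt(va + eps)
  nhat <- zc / sd
  list(out = sweep(nhat, 2L, gain, `*`) + rep(bias, each = nrow(Z)),
       nhat = nhat, sd = sd)
}

# Full forward pass, keeping intermediates when `keep = TRUE` (training) and
# applying dropout only when a mask-generating RNG stream is supplied.
forwardPair <- function(EA, EB, params, config = params$config,
                        keep = FALSE, dropout = FALSE) {
  ca <- crossAttention(EA, EB, params, config)
  Z <- ca$attended
  ln <- layerNormRows(Z, params$lnGain, params$lnBias)
  pre1 <- ln$out %*% params$mlpW1 + rep(params$mlpB1, each = nrow(Z))
  H1 <- pmax(pre1, 0)
  mask <- NULL
  if (dropout && config@dropoutRate > 0) {
    mask <- matrix(stats::rbinom(length(H1), 1L, 1 - config@dropoutRate),
                   nrow(H1), ncol(H1)) / (1 - config@dropoutRate)
    H1 <- H1 * mask
  }
  u <- drop(H1 %*% params$mlpW2) + params$mlpB2
  p <- sigmoid(u)
  if (!keep) return(p)
  list(p = p, u = u, H1 = H1, pre1 = pre1, mask = mask, ln = ln, Z = Z, ca = ca)
}

#' Predict interface probabilities for one query-partner pair
#'
#' Runs the full forward pass (cross-attention, LayerNorm, classifier MLP,
#' sigmoid) in inference mode (dropout disabled) and returns one probability
#' per query residue.
#'
#' @inheritParams crossAttention
#' @param modelTag Tag recorded on the output track.
#' @return A [ResidueProbabilityTrack-class] of length `nResidues(EA)`.
#' @examples
#' cfg <- modelConfig(embedDim = 8, numHeads = 2)
#' p <- initModel(cfg, seed = 1)
#' EA <- embeddingMatrix("a", matrix(rnorm(24), 3, 8), "synthetic")
#' EB <- embeddingMatrix("b", matrix(rnorm(16), 2, 8), "synthetic")
#' probabilities(predictPair(EA, EB, p))
#' @export
predictPair <- function(EA, EB, params, config = params$config,
                        modelTag = "custom") {
  if (nResidues(EA) < 1L || nResidues(EB) < 1L)
    stop("empty-input error: sequences must have L >= 1", call. = FALSE)
  p <- forwardPair(EA, EB, params, config, keep = FALSE, dropout = FALSE)
  probabilityTrack(sequenceId(EA), p, sequenceId(EB), modelTag)
}

#' Count trainable parameters of a configuration
#'
#' Splits the parameter budget into the cross-attention block (Q/K/V/output
#' projections with biases, plus LayerNorm gain and bias) and the classifier
#' MLP (both layers with biases). At the default configuration (d = 1280,
#' 16 heads, hidden width 1280) the total is 8,202,241 — 8.20 M — with
#' roughly 80% of capacity in the attention block.
#'
#' @param config A [ModelConfig-class].
#' @return Named numeric vector with `attention_block`, `mlp_block`, `total`.
#' @examples
#' countParameters(modelConfig(embedDim = 8, numHeads = 2, mlpHidden = 8))
#' @export
countParameters <- function(config) {
  validObject(config)
  d <- as.numeric(config@embedDim); m <- as.numeric(config@mlpHidden)
  attention <- 4 * (d * d + d) + 2 * d   # Q/K/V/O projections + LayerNorm
  mlp <- (d * m + m) + (m * 1 + 1)
  c(attention_block = attention, mlp_block = mlp, total = attention + mlp)
}

# Trainable count of an instantiated parameter set (excludes config/flags).
countInstantiated <- function(params) {
  sum(vapply(paramNames(), function(nm) length(params[[nm]]), numeric(1)))
}

#' Per-head L2 norms of the Q/K/V projections
#'
#' For each attention head, the Frobenius norm of that head's d x headDim
#' column slice of the query, key and value projection matrices. Used to
#' inspect head specialisation in trained checkpoints.
#'
#' @param params `ModelParams`.
#' @param config A [ModelConfig-class].
#' @return List with `norms` (data.frame: head, projection, L2_norm) and
#'   `summary` (data.frame: projection, mean, sd).
#' @export
perHeadNorms <- function(params, config = params$config) {
  dh <- config@headDim
  proj <- list(Q = params$Wq, K = params$Wk, V = params$Wv)
  rows <- do.call(rbind, lapply(names(proj), function(pn) {
    W <- proj[[pn]]
    data.frame(
      head = seq_len(config@numHeads), projection = pn,
      L2_norm = vapply(seq_len(config@numHeads), function(h) {
        idx <- ((h - 1L) * dh + 1L):(h * dh)
        sqrt(sum(W[, idx, drop = FALSE]^2))
      }, numeric(1)))
  }))
  summ <- do.call(rbind, lapply(split(rows, rows$projection), function(df)
    data.frame(projection = df$projection[1L], mean = mean(df$L2_norm),
               sd = stats::sd(df$L2_norm))))
  rownames(summ) <- NULL
  list(norms = rows[order(rows$head), ], summary = summ)
}
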