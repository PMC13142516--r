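#' @import methods
NULL

# ---------------------------------------------------------------------------
# Model configuration
# ---------------------------------------------------------------------------

#' ModelConfig: architecture hyper-parameters of the cross-attention predictor
#'
#' Holds the dimensions and switches of the partner-aware cross-attention
#' model. The full-scale configuration (the default) uses 1280-dimensional
#' per-residue embeddings split across 16 attention heads of 80 dimensions
#' each, and a classifier MLP whose hidden width equals the embedding
#' dimension.
#'
#' @slot embedDim Embedding dimension d; every projection is d x d.
#' @slot numHeads Number of attention heads; must divide `embedDim`.
#' @slot headDim Per-head dimension, `embedDim / numHeads`.
#' @slot mlpHidden Hidden width of the two-layer classifier MLP.
#' @slot dropoutRate Dropout rate applied inside the MLP during training
#'   only; in `[0, 1)`.
#' @slot attentionScaleMode Either `"per_head_sqrt"` (divide attention logits
#'   by sqrt(headDim), standard multi-head practice, the default) or
#'   `"full_dim_sqrt"` (divide by sqrt(embedDim)).
#' @slot useResidual Whether a residual connection adds the raw query
#'   embedding to the attended representation before LayerNorm. Off by
#'   default: the architecture routes query information through the
#'   attention weights only.
#' @slot outputBiasInit Initial value of the final output bias (logit scale).
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(
    embedDim = "integer", numHeads = "integer", headDim = "integer",
    mlpHidden = "integer", dropoutRate = "numeric",
    attentionScaleMode = "character", useResidual = "logical",
    outputBiasInit = "numeric"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@embedDim < 1L) msg <- c(msg, "embedDim must be >= 1")
  if (object@numHeads < 1L) msg <- c(msg, "numHeads must be >= 1")
  if (object@embedDim %% object@numHeads != 0L)
    msg <- c(msg, sprintf("embedDim (%d) not divisible by numHeads (%d)",
                          object@embedDim, object@numHeads))
  if (object@headDim * object@numHeads != object@embedDim)
    msg <- c(msg, "headDim * numHeads must equal embedDim")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (!object@attentionScaleMode %in% c("per_head_sqrt", "full_dim_sqrt"))
    msg <- c(msg, "attentionScaleMode must be per_head_sqrt or full_dim_sqrt")
  if (length(msg)) msg else TRUE
})

#' Create a model configuration
#'
#' @param embedDim Embedding dimension d (default 1280).
#' @param numHeads Number of attention heads (default 16); must divide
#'   `embedDim`.
#' @param mlpHidden Classifier hidden width (default `embedDim`; this is the
#'   width that yields the documented 8.20 M-parameter full-scale model).
#' @param dropoutRate MLP dropout rate during training (default 0.10).
#' @param attentionScaleMode `"per_head_sqrt"` (default) or `"full_dim_sqrt"`.
#' @param useResidual Add a query residual before LayerNorm (default FALSE).
#' @param outputBiasInit Initial output bias (default 0).
#' @return A [ModelConfig-class] object.
#' @examples
#' cfg <- modelConfig(embedDim = 8, numHeads = 2)
#' headDim(cfg)
#' @export
modelConfig <- function(embedDim = 1280L, numHeads = 16L, mlpHidden = embedDim,
                        dropoutRate = 0.10,
                        attentionScaleMode = c("per_head_sqrt", "full_dim_sqrt"),
                        useResidual = FALSE, outputBiasInit = 0) {
  embedDim <- as.integer(embedDim); numHeads <- as.integer(numHeads)
  if (embedDim %% numHeads != 0L)
    stop("configuration error: embedDim (", embedDim,
         ") is not divisible by numHeads (", numHeads, ")", call. = FALSE)
  new("ModelConfig",
      embedDim = embedDim, numHeads = numHeads,
      headDim = embedDim %/% numHeads,
      mlpHidden = as.integer(mlpHidden),
      dropoutRate = dropoutRate,
      attentionScaleMode = match.arg(attentionScaleMode),
      useResidual = isTRUE(useResidual),
      outputBiasInit = outputBiasInit)
}

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig: d =", object@embedDim, "| heads =", object@numHeads,
      "(headDim", object@headDim, ") | mlpHidden =", object@mlpHidden, "\n")
  cat("  scale:", object@attentionScaleMode,
      "| dropout:", object@dropoutRate,
      "| residual:", object@useResidual, "\n")
})

# ---------------------------------------------------------------------------
# Embedding matrices
# ---------------------------------------------------------------------------

#' EmbeddingMatrix: per-residue embedding of one protein sequence
#'
#' An L x d real matrix whose i-th row is the embedding of the i-th residue
#' (1-based residue position i maps to row i).
#'
#' @slot sequenceId Sequence identifier.
#' @slot values L x d numeric matrix with finite entries.
#' @slot source One of `"plm"`, `"synthetic"`, `"file"`.
#' @exportClass EmbeddingMatrix
setClass("EmbeddingMatrix",
  representation(sequenceId = "character", values = "matrix",
                 source = "character"))

setValidity("EmbeddingMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) < 1L) msg <- c(msg, "embedding must have L >= 1 rows")
  if (!all(is.finite(object@values))) msg <- c(msg, "embedding entries must be finite")
  if (!object@source %in% c("plm", "synthetic", "file"))
    msg <- c(msg, "source must be plm, synthetic or file")
  if (length(msg)) msg else TRUE
})

#' Construct an EmbeddingMatrix
#' @param sequenceId Identifier of the embedded sequence.
#' @param values Numeric L x d matrix (row i = residue i).
#' @param source Provenance tag: `"plm"`, `"synthetic"` or `"file"`.
#' @return An [EmbeddingMatrix-class] object.
#' @export
embeddingMatrix <- function(sequenceId, values, source = "file") {
  new("EmbeddingMatrix", sequenceId = as.character(sequenceId),
      values = as.matrix(values), source = source)
}

setMethod("show", "EmbeddingMatrix", function(object) {
  cat("EmbeddingMatrix", object@sequenceId, ":", nrow(object@values), "residues x",
      ncol(object@values), "dims (", object@source, ")\n")
})

# ---------------------------------------------------------------------------
# Probability and label tracks
# ---------------------------------------------------------------------------

#' ResidueProbabilityTrack: per-residue interaction probabilities
#'
#' The model output for one (query, partner) pair: a probability in `[0, 1]`
#' for every residue of the query, stating how likely that residue is to be
#' part of the interface with the given partner.
#'
#' @slot sequenceId Query sequence identifier.
#' @slot probabilities Numeric vector of length L, values in `[0, 1]`.
#' @slot partnerId Partner sequence identifier.
#' @slot modelTag Free-text tag of the producing model (e.g.
#'   `"receptor_centric"`).
#' @exportClass ResidueProbabilityTrack
setClass("ResidueProbabilityTrack",
  representation(sequenceId = "character", probabilities = "numeric",
                 partnerId = "character", modelTag = "character"))

setValidity("ResidueProbabilityTrack", function(object) {
  p <- object@probabilities
  if (length(p) < 1L) return("track must have length >= 1")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    return("probabilities must be finite and in [0, 1]")
  TRUE
})

#' Construct a ResidueProbabilityTrack
#' @param sequenceId Query identifier.
#' @param probabilities Numeric vector in `[0, 1]`, one entry per residue.
#' @param partnerId Partner identifier.
#' @param modelTag Model tag string.
#' @return A [ResidueProbabilityTrack-class] object.
#' @export
probabilityTrack <- function(sequenceId, probabilities, partnerId = NA_character_,
                             modelTag = "custom") {
  new("ResidueProbabilityTrack", sequenceId = as.character(sequenceId),
      probabilities = as.numeric(probabilities),
      partnerId = as.character(partnerId), modelTag = modelTag)
}

setMethod("show", "ResidueProbabilityTrack", function(object) {
  cat("ResidueProbabilityTrack", object@sequenceId, "vs", object@partnerId,
      ":", length(object@probabilities), "residues; mean p =",
      signif(mean(object@probabilities), 3), "\n")
})

#' InterfaceLabelTrack: binary interface annotation on a parent sequence
#'
#' Binary interface labels mapped onto a full-length parent sequence together
#' with a coverage mask marking positions resolved in the source structure.
#' A position can only carry a label where it is covered.
#'
#' @slot parentId Parent (e.g. UniProt) identifier.
#' @slot labels Integer 0/1 vector of length `parentLength`.
#' @slot coverageMask Integer 0/1 vector of length `parentLength`.
#' @exportClass InterfaceLabelTrack
setClass("InterfaceLabelTrack",
  representation(parentId = "character", labels = "integer",
                 coverageMask = "integer"))

setValidity("InterfaceLabelTrack", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@coverageMask))
    msg <- c(msg, "labels and coverageMask must have equal length")
  if (!all(object@labels %in% c(0L, 1L)) || !all(object@coverageMask %in% c(0L, 1L)))
    msg <- c(msg, "labels and coverageMask must be 0/1")
  if (any(object@labels == 1L & object@coverageMask == 0L))
    msg <- c(msg, "label present at an unresolved (uncovered) position")
  if (length(msg)) msg else TRUE
})

#' Construct an InterfaceLabelTrack
#' @param parentId Parent sequence identifier.
#' @param labels 0/1 vector, 1 = interface residue.
#' @param coverageMask 0/1 vector, 1 = position resolved in the structure;
#'   defaults to all-covered.
#' @return An [InterfaceLabelTrack-class] object.
#' @export
interfaceLabelTrack <- function(parentId, labels,
                                coverageMask = rep(1L, length(labels))) {
  new("InterfaceLabelTrack", parentId = as.character(parentId),
      labels = as.integer(labels), coverageMask = as.integer(coverageMask))
}

setMethod("show", "InterfaceLabelTrack", function(object) {
  cat("InterfaceLabelTrack", object@parentId, ":", length(object@labels),
      "positions,", sum(object@labels), "interface,",
      sum(object@coverageMask), "covered\n")
})

# ---------------------------------------------------------------------------
# Structures and confusion counts
# ---------------------------------------------------------------------------

#' ChainStructure: one polypeptide chain with atomic coordinates
#'
#' Minimal structural model used by the solvent-accessibility labeler: an
#' ordered residue list plus heavy atoms with coordinates (in Angstrom) and
#' assigned van der Waals radii.
#'
#' @slot chainId Chain identifier.
#' @slot residues `data.frame` with columns `resNo` (author numbering) and
#'   `resName` (three-letter code), one row per residue in chain order.
#' @slot atoms `data.frame` with columns `element`, `resIdx` (1-based index
#'   into `residues`), `x`, `y`, `z`, `radius`.
#' @exportClass ChainStructure
setClass("ChainStructure",
  representation(chainId = "character", residues = "data.frame",
                 atoms = "data.frame"))

setValidity("ChainStructure", function(object) {
  msg <- character()
  a <- object@atoms
  need <- c("element", "resIdx", "x", "y", "z", "radius")
  if (!all(need %in% names(a))) msg <- c(msg, "atoms must have element/resIdx/x/y/z/radius")
  else {
    if (nrow(a) > 0 && (any(a$resIdx < 1L) || any(a$resIdx > nrow(object@residues))))
      msg <- c(msg, "atom references a non-existent residue")
    if (nrow(a) > 0 && !all(is.finite(c(a$x, a$y, a$z, a$radius))))
      msg <- c(msg, "atom coordinates and radii must be finite")
  }
  if (!all(c("resNo", "resName") %in% names(object@residues)))
    msg <- c(msg, "residues must have resNo and resName")
  if (length(msg)) msg else TRUE
})

#' Construct a ChainStructure
#' @param chainId Chain identifier.
#' @param residues data.frame(resNo, resName) in chain order.
#' @param atoms data.frame(element, resIdx, x, y, z, radius).
#' @return A [ChainStructure-class] object.
#' @export
chainStructure <- function(chainId, residues, atoms) {
  new("ChainStructure", chainId = as.character(chainId),
      residues = residues, atoms = atoms)
}

setMethod("show", "ChainStructure", function(object) {
  cat("ChainStructure", object@chainId, ":", nrow(object@residues),
      "residues,", nrow(object@atoms), "atoms\n")
})

#' ConfusionCounts: 2x2 confusion tallies at a probability cutoff
#'
#' @slot TP,FP,FN,TN Non-negative integer counts.
#' @slot cutoff Probability cutoff used for the positive call (inclusive:
#'   p >= cutoff is positive).
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
  representation(TP = "numeric", FP = "numeric", FN = "numeric",
                 TN = "numeric", cutoff = "numeric"))

setValidity("ConfusionCounts", function(object) {
  cts <- c(object@TP, object@FP, object@FN, object@TN)
  if (any(cts < 0)) return("counts must be non-negative")
  if (sum(cts) <= 0) return("total count must be positive")
  TRUE
})

#' Construct ConfusionCounts
#' @param TP,FP,FN,TN Non-negative counts.
#' @param cutoff Probability cutoff the counts were tallied at (default 0.5).
#' @return A [ConfusionCounts-class] object.
#' @export
confusionCounts <- function(TP, FP, FN, TN, cutoff = 0.5) {
  new("ConfusionCounts", TP = as.numeric(TP), FP = as.numeric(FP),
      FN = as.numeric(FN), TN = as.numeric(TN), cutoff = cutoff)
}

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts @", object@cutoff, ": TP", object@TP, "FP", object@FP,
      "FN", object@FN, "TN", object@TN, "\n")
})
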