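# Accessor generics for the S4 containers. Slot access stays internal;
# user code goes through these.

#' @rdname EmbeddingMatrix-class
#' @param object An object.
#' @export
setGeneric("sequenceId", function(object) standardGeneric("sequenceId"))
#' @rdname EmbeddingMatrix-class
#' @export
setMethod("sequenceId", "EmbeddingMatrix", function(object) object@sequenceId)
#' @rdname ResidueProbabilityTrack-class
#' @export
setMethod("sequenceId", "ResidueProbabilityTrack", function(object) object@sequenceId)

#' @rdname EmbeddingMatrix-class
#' @export
setGeneric("embValues", function(object) standardGeneric("embValues"))
#' @rdname EmbeddingMatrix-class
#' @export
setMethod("embValues", "EmbeddingMatrix", function(object) object@values)

#' @rdname EmbeddingMatrix-class
#' @export
setGeneric("nResidues", function(object) standardGeneric("nResidues"))
#' @rdname EmbeddingMatrix-class
#' @export
setMethod("nResidues", "EmbeddingMatrix", function(object) nrow(object@values))
#' @rdname ResidueProbabilityTrack-class
#' @export
setMethod("nResidues", "ResidueProbabilityTrack",
          function(object) length(object@probabilities))
#' @rdname InterfaceLabelTrack-class
#' @export
setMethod("nResidues", "InterfaceLabelTrack", function(object) length(object@labels))
#' @rdname ChainStructure-class
#' @export
setMethod("nResidues", "ChainStructure", function(object) nrow(object@residues))

#' @rdname ResidueProbabilityTrack-class
#' @param object An object.
#' @export
setGeneric("probabilities", function(object) standardGeneric("probabilities"))
#' @rdname ResidueProbabilityTrack-class
#' @export
setMethod("probabilities", "ResidueProbabilityTrack",
          function(object) object@probabilities)

#' @rdname ResidueProbabilityTrack-class
#' @export
setGeneric("partnerId", function(object) standardGeneric("partnerId"))
#' @rdname ResidueProbabilityTrack-class
#' @export
setMethod("partnerId", "ResidueProbabilityTrack", function(object) object@partnerId)

#' @rdname InterfaceLabelTrack-class
#' @param object An object.
#' @export
setGeneric("interfaceLabels", function(object) standardGeneric("interfaceLabels"))
#' @rdname InterfaceLabelTrack-class
#' @export
setMethod("interfaceLabels", "InterfaceLabelTrack", function(object) object@labels)

#' @rdname InterfaceLabelTrack-class
#' @export
setGeneric("coverageMask", function(object) standardGeneric("coverageMask"))
#' @rdname InterfaceLabelTrack-class
#' @export
setMethod("coverageMask", "InterfaceLabelTrack", function(object) object@coverageMask)

#' @rdname ModelConfig-class
#' @param object An object.
#' @export
setGeneric("embedDim", function(object) standardGeneric("embedDim"))
#' @rdname ModelConfig-class
#' @export
setMethod("embedDim", "ModelConfig", function(object) object@embedDim)
#' @rdname EmbeddingMatrix-class
#' @export
setMethod("embedDim", "EmbeddingMatrix", function(object) ncol(object@values))

#' @rdname ModelConfig-class
#' @export
setGeneric("numHeads", function(object) standardGeneric("numHeads"))
#' @rdname ModelConfig-class
#' @export
setMethod("numHeads", "ModelConfig", function(object) object@numHeads)

#' @rdname ModelConfig-class
#' @export
setGeneric("headDim", function(object) standardGeneric("headDim"))
#' @rdname ModelConfig-class
#' @export
setMethod("headDim", "ModelConfig", function(object) object@headDim)

#' @rdname ChainStructure-class
#' @param object An object.
#' @export
setGeneric("chainId", function(object) standardGeneric("chainId"))
#' @rdname ChainStructure-class
#' @export
setMethod("chainId", "ChainStructure", function(object) object@chainId)

#' @rdname ChainStructure-class
#' @export
setGeneric("chainAtoms", function(object) standardGeneric("chainAtoms"))
#' @rdname ChainStructure-class
#' @export
setMethod("chainAtoms", "ChainStructure", function(object) object@atoms)

#' @rdname ChainStructure-class
#' @export
setGeneric("chainResidues", function(object) standardGeneric("chainResidues"))
#' @rdname ChainStructure-class
#' @export
setMethod("chainResidues", "ChainStructure", function(object) object@residues)

#' Confusion counts as a named vector
#' @rdname ConfusionCounts-class
#' @param object A [ConfusionCounts-class] object.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname ConfusionCounts-class
#' @export
setMethod("counts", "ConfusionCounts", function(object)
  c(TP = object@TP, FP = object@FP, FN = object@FN, TN = object@TN))
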