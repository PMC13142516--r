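# Mapping structure-derived interface labels onto full-length parent
# sequences via global pairwise alignment.

#' Map structure-derived labels onto a full-length parent sequence
#'
#' Globally aligns the structure-derived sequence to the parent sequence
#' (Needleman-Wunsch, BLOSUM62). Each labeled structural residue transfers
#' its label to the aligned parent position; structural residues aligned to
#' gaps are dropped with a warning and counted. The coverage mask marks
#' parent positions aligned to any structural residue. Mappings whose
#' alignment identity falls below `minIdentity` are rejected, mirroring the
#' curation rule that structures must match their parent at >= 90% identity.
#'
#' @param structureLabels 0/1 vector over the structural residues.
#' @param structureSequence One-letter sequence of the structural chain.
#' @param parentSequence Full-length parent sequence.
#' @param parentId Identifier recorded on the output track.
#' @param minIdentity Identity floor in percent (default 90).
#' @return An [InterfaceLabelTrack-class] on the parent sequence, with
#'   attribute `droppedLabels` counting labels lost to gaps.
#' @export
mapToParent <- function(structureLabels, structureSequence, parentSequence,
                        parentId = "parent", minIdentity = 90) {
  stopifnot(length(structureLabels) == nchar(structureSequence))
  # pattern-global / subject-local: the whole structural sequence must align,
  # anywhere within the full-length parent
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(structureSequence),
    Biostrings::AAString(parentSequence),
    type = "global-local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  identity <- Biostrings::pid(aln, type = "PID1")  # identities / aligned length
  if (is.na(identity)) identity <- 0
  if (identity < minIdentity)
    stop("mapping rejected: alignment identity ", round(identity, 1),
         "% below the ", minIdentity, "% floor", call. = FALSE)
  sChars <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
  pChars <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
  sPos <- 0L
  pPos <- Biostrings::subject(aln)@range@start - 1L
  L <- nchar(parentSequence)
  labels <- integer(L); mask <- integer(L)
  dropped <- 0L
  for (k in seq_along(sChars)) {
    sGap <- sChars[k] == "-"; pGap <- pChars[k] == "-"
    if (!sGap) sPos <- sPos + 1L
    if (!pGap) pPos <- pPos + 1L
    if (!sGap && !pGap) {
      mask[pPos] <- 1L
      if (structureLabels[sPos] == 1L) labels[pPos] <- 1L
    } else if (!sGap && pGap && structureLabels[sPos] == 1L) {
      dropped <- dropped + 1L
    }
  }
  if (dropped > 0L)
    warning(dropped, " labeled structural residue(s) aligned to gaps were dropped")
  out <- interfaceLabelTrack(parentId, labels, mask)
  attr(out, "droppedLabels") <- dropped
  out
}

#' Write an interface label track as TSV
#'
#' Columns: parent_id, position (1-based), residue, label, covered.
#'
#' @param track An [InterfaceLabelTrack-class].
#' @param parentSequence Parent sequence (for the residue column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLabelTrack <- function(track, parentSequence, path) {
  df <- data.frame(parent_id = track@parentId,
                   position = seq_len(nResidues(track)),
                   residue = strsplit(parentSequence, "")[[1L]],
                   label = interfaceLabels(track),
                   covered = coverageMask(track))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interface segments as BED-like intervals
#'
#' Collapses consecutive interface labels into half-open 0-based intervals
#' (chrom = parent id), the common interchange convention for interval
#' files.
#'
#' @param track An [InterfaceLabelTrack-class].
#' @return data.frame with columns `parent_id`, `start`, `end`.
#' @export
interfaceSegments <- function(track) {
  lab <- interfaceLabels(track)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  data.frame(parent_id = track@parentId, start = starts[keep], end = ends[keep])
}
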