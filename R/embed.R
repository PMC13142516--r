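# Embedding backends: pluggable producers of EmbeddingMatrix objects.
#
# Three backends share one contract (an L x d matrix, row i = residue i):
#  * synthetic — a deterministic local-context embedder used throughout the
#    test stack. Each residue's vector is a flank-weighted sum of seeded
#    basis vectors indexed by (residue identity, offset), so identical k-mer
#    contexts give identical rows and short linear motifs are linearly
#    separable in embedding space.
#  * file — matrices precomputed elsewhere (e.g. by a protein language
#    model) and stored in the package's simple header+binary format.
#  * plm_adapter — an interface slot for a live protein language model; the
#    caller registers a function(sequence) -> matrix. The documented
#    expected checkpoint at full scale is the 650M-parameter ESM-2 model
#    producing 1280-dimensional rows with a 1022-residue context window.

#' Describe an embedding backend
#'
#' @param backend `"synthetic"`, `"file"` or `"plm_adapter"`.
#' @param embedDim Embedding dimension every emitted matrix must have.
#' @param seed Integer seed (synthetic backend only).
#' @param contextFlank Residues of flanking context on each side used by the
#'   synthetic backend (default 1: every residue is embedded from the 3-mer
#'   window centred on it, with flank contributions decaying geometrically,
#'   matching the default planted-motif length so short linear motifs are
#'   linearly separable in embedding space).
#' @param positional Include the smooth positional component (synthetic
#'   backend; default TRUE).
#' @param contextWindow Maximum sequence length a plm_adapter call may see
#'   before the chunked path is required (default 1022).
#' @param path Directory holding per-sequence embedding files (file backend).
#' @param adapter Function `function(sequence) -> L x d matrix`
#'   (plm_adapter backend).
#' @return An `EmbedderSpec` list.
#' @export
embedderSpec <- function(backend = c("synthetic", "file", "plm_adapter"),
                         embedDim = 1280L, seed = 0L, contextFlank = 1L,
                         positional = TRUE, contextWindow = 1022L,
                         path = NULL, adapter = NULL) {
  spec <- list(backend = match.arg(backend), embedDim = as.integer(embedDim),
               seed = as.integer(seed), contextFlank = as.integer(contextFlank),
               positional = isTRUE(positional),
               contextWindow = as.integer(contextWindow),
               path = path, adapter = adapter)
  class(spec) <- "EmbedderSpec"
  spec
}

validateSequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("input error: sequence must be a non-empty string", call. = FALSE)
  chars <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(chars), c(AA_ALPHABET20, "X"))
  if (length(bad))
    stop("input error: illegal residue character(s): ",
         paste(bad, collapse = ","), call. = FALSE)
  chars
}

# Seeded basis table: one d-vector per (token, offset); tokens are the 20
# amino acids plus X. When d allows (d >= 21), the 21 token vectors of each
# offset are orthonormal (a seeded random rotation of the canonical axes),
# so distinct residues at the same offset are exactly non-confusable; at
# smaller d the basis falls back to i.i.d. Gaussian vectors. Either way,
# vectors are scaled so embedding row norms are comparable across d and
# flank. Context windows are edge-clamped at chain termini.
syntheticBasis <- function(d, flank, seed) {
  tokens <- c(AA_ALPHABET20, "X")
  offsets <- (-flank):flank
  scale <- sqrt(d / (2 * flank + 1))
  withSeed(subSeed(seed, "synthetic-basis"), {
    arr <- array(0, dim = c(length(tokens), length(offsets), d),
                 dimnames = list(tokens, as.character(offsets), NULL))
    for (oi in seq_along(offsets)) {
      if (d >= length(tokens)) {
        Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
        arr[, oi, ] <- t(Q[, seq_along(tokens)]) * scale
      } else {
        arr[, oi, ] <- matrix(stats::rnorm(length(tokens) * d), length(tokens), d) *
          (scale / sqrt(d))
      }
    }
    arr
  })
}

#' Embed a protein sequence
#'
#' Produces the per-residue embedding matrix for one sequence under the
#' given backend. The synthetic backend is a pure function of
#' (sequence, embedDim, seed, contextFlank): row i is the flank-decayed sum
#' of basis vectors for the residues in the window `i - flank .. i + flank`
#' (chain ends contribute a boundary token), plus an optional low-amplitude
#' sinusoidal positional component.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet plus X.
#' @param spec An `EmbedderSpec` from [embedderSpec()].
#' @return An [EmbeddingMatrix-class] of dimension `nchar(sequence)` x
#'   `spec$embedDim`.
#' @examples
#' em <- embedSequence("ACDEF", embedderSpec("synthetic", embedDim = 8, seed = 7))
#' dim(embValues(em))
#' @export
embedSequence <- function(sequence, spec, sequenceId = "seq") {
  chars <- validateSequence(sequence)
  L <- length(chars)
  d <- spec$embedDim
  switch(spec$backend,
    synthetic = {
      flank <- spec$contextFlank
      basis <- syntheticBasis(d, flank, spec$seed)
      decay <- 0.5
      vals <- matrix(0, L, d)
      for (o in (-flank):flank) {
        idx <- pmin(pmax(seq_len(L) + o, 1L), L)   # edge-clamped window
        w <- decay^abs(o)
        vals <- vals + w * basis[chars[idx], as.character(o), , drop = TRUE]
      }
      if (spec$positional) {
        j <- seq_len(d)
        freq <- 1 / (10 ^ (2 * (j %% 8) / 8))
        pos <- 0.05 * sin(outer(seq_len(L), freq))
        vals <- vals + pos
      }
      embeddingMatrix(sequenceId, vals, "synthetic")
    },
    file = {
      if (is.null(spec$path))
        stop("file backend requires a path", call. = FALSE)
      em <- readEmbedding(file.path(spec$path, paste0(sequenceId, ".emb")))
      if (ncol(embValues(em)) != d)
        stop("embedding file dimension ", ncol(embValues(em)),
             " does not match declared embedDim ", d, call. = FALSE)
      em
    },
    plm_adapter = {
      if (L > spec$contextWindow)
        stop("contract error: sequence length ", L, " exceeds context window ",
             spec$contextWindow, "; use the chunked inference path", call. = FALSE)
      if (is.null(spec$adapter))
        stop("no PLM adapter registered on this EmbedderSpec", call. = FALSE)
      vals <- spec$adapter(sequence)
      if (!is.matrix(vals) || nrow(vals) != L || ncol(vals) != d)
        stop("adapter returned a matrix not matching the L x d contract",
             call. = FALSE)
      embeddingMatrix(sequenceId, vals, "plm")
    })
}

# Single-token fetch from a 3D basis array for a vector of tokens at one
# offset; returns an L x d matrix.
# (handled inline above via matrix indexing of the first two dims)

#' Write / read the package's embedding file format
#'
#' One file per sequence: a single JSON header line carrying
#' `{"id":..., "L":..., "d":...}` followed by the matrix values as
#' little-endian doubles in row-major order.
#'
#' @param em An [EmbeddingMatrix-class].
#' @param path Output file path.
#' @return `writeEmbedding` returns `path` invisibly; `readEmbedding`
#'   returns an [EmbeddingMatrix-class] with source `"file"`.
#' @export
writeEmbedding <- function(em, path) {
  vals <- embValues(em)
  hdr <- jsonlite::toJSON(list(id = sequenceId(em), L = nrow(vals),
                               d = ncol(vals)), auto_unbox = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeBin(as.numeric(t(vals)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- jsonlite::fromJSON(readLines(con, n = 1L))
  vals <- readBin(con, "numeric", n = hdr$L * hdr$d, size = 8L,
                  endian = "little")
  embeddingMatrix(hdr$id, matrix(vals, hdr$L, hdr$d, byrow = TRUE), "file")
}

#' Read a (possibly wrapped) multi-record protein FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]; translation stop
#' characters (`*`) are stripped and names are truncated at the first
#' whitespace.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- gsub("\\*", "", as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastaSequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
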