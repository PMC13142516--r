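# Chunked inference for sequences longer than the embedder's context window:
# overlapping windows (default 1022 residues, stride 512), every query chunk
# cross-attended against every partner chunk, and per-residue probabilities
# aggregated by max pooling. Intervals are 0-based half-open internally;
# emitted files are 1-based.

#' Plan overlapping chunks for a long sequence
#'
#' Window starts run 0, stride, 2*stride, ... while a full window still ends
#' before L; a final chunk is end-aligned at `max(0, L - window)` so the last
#' residue is always covered and no padding is fabricated. For
#' `L <= window` the plan is the single chunk `[0, L)`.
#'
#' @param L Sequence length (>= 1).
#' @param window Window size in residues (default 1022, the context limit of
#'   the 650M-parameter embedder the defaults are sized for).
#' @param stride Stride between window starts (default 512); must not exceed
#'   `window`.
#' @return List with `window`, `stride`, and `chunks` — an n x 2 matrix of
#'   0-based half-open `[start, end)` intervals.
#' @examples
#' planChunks(2048)$chunks
#' @export
planChunks <- function(L, window = 1022L, stride = 512L) {
  L <- as.integer(L); window <- as.integer(window); stride <- as.integer(stride)
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (stride < 1L || stride > window)
    stop("configuration error: need 1 <= stride <= window (stride > window would leave gaps)",
         call. = FALSE)
  starts <- integer(0)
  s <- 0L
  while (s + window < L) { starts <- c(starts, s); s <- s + stride }
  starts <- c(starts, max(0L, L - window))
  chunks <- cbind(start = starts, end = pmin(starts + window, L))
  list(window = window, stride = stride, chunks = chunks)
}

#' Max-pool per-residue predictions across overlapping chunks
#'
#' @param tracks List of `list(interval = c(start, end), values = numeric)`
#'   with 0-based half-open intervals and one value per covered position.
#' @param L Full sequence length.
#' @return Numeric vector of length L; position i is the max over all chunk
#'   predictions covering it.
#' @export
aggregateMax <- function(tracks, L) {
  out <- rep(-Inf, L)
  for (tr in tracks) {
    iv <- tr$interval
    len <- iv[2L] - iv[1L]
    if (length(tr$values) != len)
      stop("shape error: track values do not match interval length", call. = FALSE)
    pos <- (iv[1L] + 1L):iv[2L]
    out[pos] <- pmax(out[pos], tr$values)
  }
  if (any(!is.finite(out)))
    stop("coverage error: positions ",
         paste(which(!is.finite(out)), collapse = ","),
         " received no prediction", call. = FALSE)
  out
}

#' Predict a long query-partner pair through chunked inference
#'
#' Both sequences are cut into overlapping windows; every (query chunk,
#' partner chunk) combination is run through [predictPair()] and each query
#' position takes the maximum probability over all combinations covering it.
#' When both sequences fit in one window this reduces bitwise to a direct
#' [predictPair()] call. Embedding rows are sliced from the full-length
#' matrices per chunk, which is exact for the local-context backends shipped
#' here.
#'
#' @inheritParams predictPair
#' @param window,stride Chunking parameters (defaults 1022 / 512).
#' @return A [ResidueProbabilityTrack-class] of length `nResidues(EA)`.
#' @export
predictLongPair <- function(EA, EB, params, config = params$config,
                            window = 1022L, stride = 512L,
                            modelTag = "custom") {
  planA <- planChunks(nResidues(EA), window, stride)
  planB <- planChunks(nResidues(EB), window, stride)
  XA <- embValues(EA); XB <- embValues(EB)
  tracks <- list()
  for (i in seq_len(nrow(planA$chunks))) {
    ivA <- planA$chunks[i, ]
    subA <- embeddingMatrix(sequenceId(EA),
                            XA[(ivA[1L] + 1L):ivA[2L], , drop = FALSE],
                            EA@source)
    best <- NULL
    for (j in seq_len(nrow(planB$chunks))) {
      ivB <- planB$chunks[j, ]
      subB <- embeddingMatrix(sequenceId(EB),
                              XB[(ivB[1L] + 1L):ivB[2L], , drop = FALSE],
                              EB@source)
      p <- probabilities(predictPair(subA, subB, params, config))
      best <- if (is.null(best)) p else pmax(best, p)
    }
    tracks[[length(tracks) + 1L]] <- list(interval = ivA, values = best)
  }
  probabilityTrack(sequenceId(EA), aggregateMax(tracks, nResidues(EA)),
                   sequenceId(EB), modelTag)
}
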