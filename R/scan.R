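# Prediction driver and the partner-ensemble interface scan.

#' Predict probability tracks for a list of query-partner pairs
#'
#' Reads sequences from FASTA, resolves the pair list, embeds every
#' sequence, routes long sequences through chunked inference automatically,
#' and writes one TSV row per residue: sequence_id, position (1-based),
#' residue, probability, binary_call.
#'
#' @param queryFasta,partnerFasta FASTA paths (a partner may live in the
#'   query file and vice versa; both files are pooled for ID resolution).
#' @param pairsTsv TSV with columns `query_id`, `partner_id`.
#' @param checkpointPath Path written by [saveCheckpoint()].
#' @param embedder An `EmbedderSpec`; its dimension must match the
#'   checkpoint.
#' @param outPath Output TSV path.
#' @param window,stride Chunking parameters.
#' @param cutoff Probability cutoff for the `binary_call` column.
#' @param scrambleSeed If non-NULL, partners are scrambled with this seed
#'   before prediction (the scrambled-partner control; the prediction path
#'   itself is unchanged).
#' @return Invisible list of [ResidueProbabilityTrack-class], named
#'   `query|partner`; the TSV is written as a side effect when `outPath` is
#'   non-NULL.
#' @export
runPredict <- function(queryFasta, partnerFasta, pairsTsv, checkpointPath,
                       embedder, outPath = NULL, window = 1022L,
                       stride = 512L, cutoff = 0.5, scrambleSeed = NULL) {
  seqs <- c(readFastaSequences(queryFasta),
            readFastaSequences(partnerFasta))
  seqs <- seqs[!duplicated(names(seqs))]
  pairs <- utils::read.delim(pairsTsv, stringsAsFactors = FALSE)
  ck <- loadCheckpoint(checkpointPath)
  if (embedder$embedDim != embedDim(ck$config))
    stop("config error: embedder dimension ", embedder$embedDim,
         " incompatible with checkpoint d = ", embedDim(ck$config),
         call. = FALSE)
  missing <- setdiff(unique(c(pairs$query_id, pairs$partner_id)), names(seqs))
  if (length(missing))
    stop("named-ID error: sequence(s) not found in FASTA inputs: ",
         paste(missing, collapse = ","), call. = FALSE)
  tracks <- list()
  for (i in seq_len(nrow(pairs))) {
    qid <- pairs$query_id[i]; pid <- pairs$partner_id[i]
    pSeq <- seqs[[pid]]
    if (!is.null(scrambleSeed))
      pSeq <- scramblePartner(pSeq, subSeed(scrambleSeed, pid))
    EA <- embedSequence(seqs[[qid]], embedder, qid)
    EB <- embedSequence(pSeq, embedder, pid)
    tr <- if (nResidues(EA) > window || nResidues(EB) > window)
      predictLongPair(EA, EB, ck$params, ck$config, window, stride,
                      modelTag = ck$modelTag)
    else predictPair(EA, EB, ck$params, ck$config, modelTag = ck$modelTag)
    tracks[[paste(qid, pid, sep = "|")]] <- tr
  }
  if (!is.null(outPath)) {
    rows <- do.call(rbind, lapply(tracks, function(tr) {
      p <- probabilities(tr)
      data.frame(sequence_id = sequenceId(tr), partner_id = partnerId(tr),
                 position = seq_along(p),
                 residue = strsplit(seqs[[sequenceId(tr)]], "")[[1L]],
                 probability = p, binary_call = as.integer(p >= cutoff))
    }))
    utils::write.table(rows, outPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(tracks)
}

#' Partner-ensemble interface scan
#'
#' Predicts the query against every partner in a set and summarises, per
#' query position: the median probability, the interquartile range, and the
#' fraction of partners for which the position reaches probability >=
#' `threshold` (inclusive). This is the summary used to profile recurrent
#' interface usage of a hub protein across its interactome.
#'
#' @param tracks List of [ResidueProbabilityTrack-class], all for the same
#'   query (e.g. from [runPredict()]); alternatively supply raw probability
#'   vectors.
#' @param threshold Probability threshold for the partner fraction
#'   (default 0.10).
#' @return A `ScanSummary` data.frame: position, median, q1, q3,
#'   fraction_ge_threshold; attributes `queryId`, `nPartners`, `threshold`.
#' @export
scanPartners <- function(tracks, threshold = 0.10) {
  if (!length(tracks)) stop("data error: empty partner set", call. = FALSE)
  probs <- lapply(tracks, function(tr)
    if (is(tr, "ResidueProbabilityTrack")) probabilities(tr) else as.numeric(tr))
  L <- unique(vapply(probs, length, integer(1)))
  if (length(L) != 1L)
    stop("all tracks must cover the same query length", call. = FALSE)
  M <- do.call(rbind, probs)   # partners x positions
  qs <- apply(M, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75), type = 7L)
  out <- data.frame(position = seq_len(L),
                    median = qs[2L, ], q1 = qs[1L, ], q3 = qs[3L, ],
                    fraction_ge_threshold = colMeans(M >= threshold))
  qid <- if (is(tracks[[1L]], "ResidueProbabilityTrack"))
    sequenceId(tracks[[1L]]) else "query"
  structure(out, queryId = qid, nPartners = nrow(M), threshold = threshold,
            class = c("ScanSummary", "data.frame"))
}

#' @export
print.ScanSummary <- function(x, ...) {
  cat("ScanSummary:", attr(x, "queryId"), "across", attr(x, "nPartners"),
      "partners (threshold", attr(x, "threshold"), ")\n")
  NextMethod()
}

#' Write a scan summary as TSV
#'
#' Columns: position, residue, median, q1, q3, fraction.
#'
#' @param scan A `ScanSummary`.
#' @param querySequence Query sequence (for the residue column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeScanSummary <- function(scan, querySequence, path) {
  df <- data.frame(position = scan$position,
                   residue = strsplit(querySequence, "")[[1L]],
                   median = scan$median, q1 = scan$q1, q3 = scan$q3,
                   fraction = scan$fraction_ge_threshold)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
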