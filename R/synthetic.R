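# Synthetic, label-complete fixtures: paired sequences with planted
# partner-conditioned interface residues at realistic class imbalance, and
# toy multi-chain coordinate sets for the solvent-accessibility labeler.
#
# The planted rule mimics short-linear-motif-mediated binding: a query
# residue is an interface residue iff it lies inside an occurrence of a
# planted query motif AND the coupled partner motif occurs anywhere in the
# partner. Scrambling the partner therefore destroys the condition — the
# property the scrambled-partner control measures.

DEFAULT_MOTIFS <- c("HDH", "CRC", "ALA", "IEI")

#' Define a planted motif rule
#'
#' @param k Motif length (default 3).
#' @param motifPairs List of `c(queryMotif, partnerMotif)` couples. The
#'   default is a library of four self-complementary, patterned couples
#'   (`HDH`, `CRC`, `ALA`, `IEI`): the partner motif is the query motif
#'   itself, so the learnable rule is one shared content-matching rule — a
#'   query motif is "recognised" when the same short pattern occurs, in
#'   order, in the partner — and the a-b-a shape over a couple-unique
#'   letter pair means any two of a motif's letters determine the whole
#'   motif. See the methods vignette for why each property matters.
#' @param backgroundPositiveRate Extra positives planted independently of
#'   motifs (default 0).
#' @param labelNoise Probability of flipping each emitted label (default 0;
#'   must be < 0.5).
#' @return A `PlantedRule` list.
#' @export
plantedRule <- function(k = 3L,
                        motifPairs = lapply(DEFAULT_MOTIFS,
                                            function(m) c(m, m)),
                        backgroundPositiveRate = 0, labelNoise = 0) {
  k <- as.integer(k)
  stopifnot(k >= 1L, labelNoise >= 0, labelNoise < 0.5)
  if (anyDuplicated(vapply(motifPairs, paste, character(1), collapse = "|")))
    stop("motif pairs must be distinct", call. = FALSE)
  for (mp in motifPairs)
    stopifnot(length(mp) == 2L, all(nchar(mp) == k))
  structure(list(k = k, motifPairs = motifPairs,
                 backgroundPositiveRate = backgroundPositiveRate,
                 labelNoise = labelNoise),
            class = "PlantedRule")
}

# All positions covered by (possibly overlapping) occurrences of `motif`.
motifCover <- function(s, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1L]]
  cov <- logical(nchar(s))
  if (hits[1L] != -1L)
    for (h in hits) cov[h:(h + nchar(motif) - 1L)] <- TRUE
  cov
}

# Ground-truth labels by direct string matching of the motif couples.
plantedLabels <- function(query, partner, rule) {
  lab <- logical(nchar(query))
  for (mp in rule$motifPairs)
    if (grepl(mp[2L], partner, fixed = TRUE))
      lab <- lab | motifCover(query, mp[1L])
  as.integer(lab)
}

randomSeq <- function(L) paste(sample(AA_ALPHABET20, L, replace = TRUE),
                               collapse = "")

# Overwrite the motif's letters one at a time at distinct random positions,
# so the sequence gains the motif's composition without any consistent
# k-mer: a composition match that carries no order signal.
plantScattered <- function(s, motif) {
  chars <- strsplit(motif, "")[[1L]]
  L <- nchar(s)
  if (L < length(chars)) return(s)
  at <- sample.int(L, length(chars))
  out <- strsplit(s, "")[[1L]]
  out[at] <- chars
  paste(out, collapse = "")
}

plantMotif <- function(s, motif) {
  L <- nchar(s); k <- nchar(motif)
  if (L < k) return(s)
  at <- sample.int(L - k + 1L, 1L)
  paste0(substr(s, 1L, at - 1L), motif, substr(s, at + k, L))
}

#' Generate a paired-sequence dataset with planted partner-conditioned labels
#'
#' Queries are built as tilings of query motifs drawn from the rule's couple
#' library, each motif followed by one random spacer residue (plus a short
#' random remainder), so that the query sequence by itself carries
#' essentially no information about which residues will be labeled —
#' mimicking short-linear-motif biology, where a peptide is full of
#' candidate motifs and the partner decides which are used. For each couple
#' present in a query, the coupled partner motif is planted, in order, into
#' the partner with a calibrated activation probability; inactive couples
#' instead have their motif's letters scattered at random partner
#' positions, so partner composition is identical across active and
#' inactive pairs and only residue order is informative. Labels are then
#' recomputed from the final strings by independent motif matching (so
#' chance partner occurrences activate a couple consistently with the
#' rule). The activation rate is tuned so the realised positive fraction
#' lands within 30% (relative) of `positiveRateTarget`; generation fails
#' after bounded retries if the target is unsatisfiable.
#'
#' @param nPairs Number of pairs.
#' @param queryLenRange,partnerLenRange Integer ranges (inclusive) for
#'   sequence lengths. The defaults give queries long enough to carry
#'   several candidate motifs (40-80 residues) and partners in the
#'   single-domain length range (60-120 residues).
#' @param rule A `PlantedRule`.
#' @param positiveRateTarget Target positive-residue fraction over all query
#'   residues, in (0, 0.2); the default 0.03 sits inside the ~1.7-3.5%
#'   class-imbalance band of curated interface data.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return List with `pairs` (each: `queryId`, `partnerId`, `query`,
#'   `partner`, `labels`) and `meta` (rule, seed, realised rate, activation
#'   rate).
#' @export
generatePairDataset <- function(nPairs, queryLenRange = c(40L, 80L),
                                partnerLenRange = c(60L, 120L),
                                rule = plantedRule(),
                                positiveRateTarget = 0.03, seed = 0L) {
  stopifnot(positiveRateTarget > 0, positiveRateTarget < 0.2,
            queryLenRange[1L] >= rule$k, partnerLenRange[1L] >= rule$k)
  k <- rule$k
  unit <- k + 1L                    # motif + one random spacer residue
  coverage <- k / unit
  # chance rate of a specific k-mer occurring in a random partner
  chance <- (mean(partnerLenRange) - k + 1) / 20^k
  pActive <- max(0.005, min(0.95,
    (positiveRateTarget / coverage - chance) / (1 - chance)))
  for (attempt in 1:20) {
    ds <- withSeed(subSeed(seed, paste0("pairs", attempt)), {
      pairs <- vector("list", nPairs)
      nCouples <- length(rule$motifPairs)
      for (i in seq_len(nPairs)) {
        Lq <- sample(queryLenRange[1L]:queryLenRange[2L], 1L)
        Lp <- sample(partnerLenRange[1L]:partnerLenRange[2L], 1L)
        nTiles <- Lq %/% unit
        tileIdx <- sample.int(nCouples, nTiles, replace = TRUE)
        q <- paste0(
          paste(vapply(rule$motifPairs[tileIdx], function(mp)
            paste0(mp[1L], randomSeq(1L)), character(1)), collapse = ""),
          if (Lq %% unit > 0L) randomSeq(Lq %% unit) else "")
        p <- randomSeq(Lp)
        present <- unique(tileIdx)
        active <- present[stats::runif(length(present)) < pActive]
        # scatter first, then plant, so planted motifs survive intact
        for (ci in setdiff(present, active))
          p <- plantScattered(p, rule$motifPairs[[ci]][2L])
        for (ci in active)
          p <- plantMotif(p, rule$motifPairs[[ci]][2L])
        lab <- plantedLabels(q, p, rule)
        if (rule$backgroundPositiveRate > 0)
          lab <- as.integer(lab | (stats::runif(length(lab)) <
                                     rule$backgroundPositiveRate))
        if (rule$labelNoise > 0) {
          flip <- stats::runif(length(lab)) < rule$labelNoise
          lab[flip] <- 1L - lab[flip]
        }
        pairs[[i]] <- list(queryId = sprintf("Q%04d", i),
                           partnerId = sprintf("P%04d", i),
                           query = q, partner = p, labels = lab)
      }
      pairs
    })
    realized <- sum(vapply(ds, function(x) sum(x$labels), numeric(1))) /
      sum(vapply(ds, function(x) length(x$labels), numeric(1)))
    if (abs(realized - positiveRateTarget) <= 0.30 * positiveRateTarget)
      return(list(pairs = ds,
                  meta = list(rule = rule, seed = seed,
                              realizedPositiveRate = realized,
                              plantingRate = pActive)))
    pActive <- max(0.005, min(0.95, pActive +
      (positiveRateTarget - realized) / coverage / (1 - chance)))
  }
  stop("generation error: could not reach the positive-rate target after ",
       "bounded retries", call. = FALSE)
}

#' Write a generated pair dataset to standard formats
#'
#' FASTA for queries and partners, TSV for labels (query_id, position,
#' label), JSON for the rule and seeds.
#'
#' @param dataset Output of [generatePairDataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writePairDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qs <- vapply(dataset$pairs, `[[`, character(1), "query")
  names(qs) <- vapply(dataset$pairs, `[[`, character(1), "queryId")
  ps <- vapply(dataset$pairs, `[[`, character(1), "partner")
  names(ps) <- vapply(dataset$pairs, `[[`, character(1), "partnerId")
  writeFastaSequences(qs, file.path(dir, "queries.fasta"))
  writeFastaSequences(ps, file.path(dir, "partners.fasta"))
  lab <- do.call(rbind, lapply(dataset$pairs, function(pr)
    data.frame(query_id = pr$queryId, position = seq_along(pr$labels),
               label = pr$labels)))
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pairsTsv <- data.frame(
    query_id = names(qs), partner_id = names(ps))
  utils::write.table(pairsTsv, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- dataset$meta
  meta$rule <- unclass(meta$rule)
  meta$rule$motifPairs <- lapply(meta$rule$motifPairs, as.list)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Generate a toy two-chain complex with prescribed contacts
#'
#' Chain A is a spaced linear arrangement of single-atom residues (10
#' Angstrom apart, far beyond mutual occlusion range). Chain B places one
#' atom within occlusion distance (~4 Angstrom) of exactly the requested A
#' positions; its remaining residues sit on a parallel line >= 50 Angstrom
#' away, where they change nothing. Feeding the two chains to
#' [deltaRsaLabels()] therefore labels exactly the contact positions.
#'
#' @param nResiduesA,nResiduesB Residue counts of the two chains.
#' @param contactPositions Integer positions (1-based) on chain A to occlude;
#'   must fit within chain A and require at most `nResiduesB` atoms.
#' @param seed Deterministic jitter seed for the contact distances.
#' @return List of two [ChainStructure-class] objects named `A` and `B`.
#' @export
generateToyComplex <- function(nResiduesA, nResiduesB, contactPositions,
                               seed = 0L) {
  contactPositions <- sort(unique(as.integer(contactPositions)))
  if (length(contactPositions) &&
      (min(contactPositions) < 1L || max(contactPositions) > nResiduesA))
    stop("placement error: contact positions outside chain A", call. = FALSE)
  if (length(contactPositions) > nResiduesB)
    stop("placement error: more contacts than chain B residues", call. = FALSE)
  mkChain <- function(id, n, xyz) {
    chainStructure(id,
      residues = data.frame(resNo = seq_len(n), resName = "ALA"),
      atoms = data.frame(element = "C", resIdx = seq_len(n),
                         x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                         radius = unname(ELEMENT_RADII["C"])))
  }
  A <- mkChain("A", nResiduesA,
               cbind(10 * seq_len(nResiduesA), 0, 0))
  dist <- withSeed(subSeed(seed, "toy-contact"),
                   stats::runif(length(contactPositions), 3.5, 4.2))
  xyzB <- matrix(0, nResiduesB, 3L)
  bIdx <- 0L
  for (ci in seq_along(contactPositions)) {
    bIdx <- bIdx + 1L
    xyzB[bIdx, ] <- c(10 * contactPositions[ci], dist[ci], 0)
  }
  if (bIdx < nResiduesB) {
    far <- seq_len(nResiduesB - bIdx)
    xyzB[(bIdx + 1L):nResiduesB, ] <- cbind(10 * far, 1000, 0)
  }
  B <- mkChain("B", nResiduesB, xyzB)
  list(A = A, B = B)
}
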