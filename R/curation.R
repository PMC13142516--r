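# Dataset curation: record filtering, sequence-identity clustering,
# leakage-free grouped splitting and disorder flagging.
#
# The unit of splitting is the focal protein (the chain whose residues are
# predicted); all pairs sharing a focal parent go to the same subset, and
# focal parents sharing > 25% pairwise identity are clustered so that no
# blind-set focal protein resembles a training one.

#' Read a BioLiP-style annotation table
#'
#' Expects a TSV with columns `pdb_id`, `receptor_chain`, `peptide_chain`,
#' `peptide_length`, `receptor_parent_ids`, `peptide_parent_ids` (semicolon
#' -separated accessions), `receptor_identity`, `peptide_identity`,
#' `is_antibody_complex` plus optional `receptor_sequence`,
#' `peptide_sequence`.
#'
#' @param path TSV path.
#' @return data.frame of complex records.
#' @export
readComplexRecords <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pdb_id", "receptor_chain", "peptide_chain", "peptide_length",
            "receptor_parent_ids", "peptide_parent_ids",
            "receptor_identity", "peptide_identity", "is_antibody_complex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: missing column(s) ", paste(miss, collapse = ","),
         call. = FALSE)
  bad <- which(!is.finite(df$peptide_length))
  if (length(bad))
    stop("parse error: malformed peptide_length at line ", bad[1L] + 1L,
         call. = FALSE)
  df
}

splitIds <- function(x) {
  ids <- strsplit(as.character(x), ";", fixed = TRUE)[[1L]]
  ids[nzchar(trimws(ids))]
}

#' Filter complex records for curation
#'
#' A record is kept iff, for the focal chain: a parent accession is present,
#' it maps to exactly one parent, sequence identity to the parent is at
#' least 90%, the complex is not flagged as an antibody-epitope complex,
#' and (for peptide ligands) the peptide is at most `maxPeptideLength`
#' residues. Every rejected record carries the single rule tag that fired
#' first, in the order listed.
#'
#' @param records data.frame from [readComplexRecords()].
#' @param focal `"receptor"` or `"peptide"` — which chain the model predicts
#'   on.
#' @param minIdentity Identity floor in percent (default 90; a record at
#'   89.9 is rejected).
#' @param maxPeptideLength Maximum admitted peptide ligand length
#'   (default 30).
#' @return List with `kept` (data.frame, plus a `focal_parent_id` column)
#'   and `rejected` (data.frame with a `reason` column: `"no-uniprot"`,
#'   `"multi-uniprot"`, `"identity<90"`, `"antibody"`, `"peptide>30"`).
#' @export
filterRecords <- function(records, focal = c("receptor", "peptide"),
                          minIdentity = 90, maxPeptideLength = 30L) {
  focal <- match.arg(focal)
  idCol <- paste0(focal, "_parent_ids")
  pidCol <- paste0(focal, "_identity")
  reasons <- character(nrow(records))
  focalIds <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    ids <- splitIds(records[[idCol]][i])
    if (length(ids) == 0L) reasons[i] <- "no-uniprot"
    else if (length(ids) > 1L) reasons[i] <- "multi-uniprot"
    else if (records[[pidCol]][i] < minIdentity)
      reasons[i] <- sprintf("identity<%g", minIdentity)
    else if (isTRUE(as.logical(records$is_antibody_complex[i])))
      reasons[i] <- "antibody"
    else if (records$peptide_length[i] > maxPeptideLength)
      reasons[i] <- sprintf("peptide>%d", maxPeptideLength)
    else focalIds[i] <- ids
  }
  keep <- reasons == ""
  kept <- records[keep, , drop = FALSE]
  kept$focal_parent_id <- focalIds[keep]
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reasons[!keep]
  list(kept = kept, rejected = rejected)
}

#' Pairwise sequence identity over a local alignment
#'
#' Smith-Waterman (BLOSUM62, gap open 11 / extend 1) identity, defined as
#' identities divided by alignment length (gaps included) — no coverage
#' requirement, so locally similar sequences score high even when lengths
#' differ.
#'
#' @param a,b Amino-acid strings.
#' @return Identity in percent (0 when no positive-scoring local alignment
#'   exists).
#' @export
pairIdentity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  if (Biostrings::nchar(aln) == 0L) return(0)
  Biostrings::pid(aln, type = "PID1")
}

#' Greedy identity clustering of focal sequences
#'
#' CD-HIT-style greedy clustering: sequences are visited longest first; a
#' sequence joins the first existing cluster whose representative shares
#' more than `threshold` percent identity ([pairIdentity()]), otherwise it
#' founds a new cluster with itself as representative.
#'
#' @param sequences Named character vector (id -> sequence).
#' @param threshold Identity threshold in percent (default 25; strictly
#'   greater joins).
#' @return data.frame with columns `id`, `cluster`, `representative`.
#' @export
clusterByIdentity <- function(sequences, threshold = 25) {
  if (!length(sequences)) stop("data error: no sequences supplied", call. = FALSE)
  ord <- order(-nchar(sequences), names(sequences))
  reps <- character(0)
  assign <- integer(length(sequences))
  names(assign) <- names(sequences)
  for (i in ord) {
    id <- names(sequences)[i]
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (pairIdentity(sequences[[reps[ci]]], sequences[[i]]) > threshold) {
        assign[id] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign[id] <- length(reps)
    }
  }
  data.frame(id = names(sequences), cluster = unname(assign[names(sequences)]),
             representative = reps[assign[names(sequences)]],
             stringsAsFactors = FALSE)
}

# Largest-remainder apportionment of n units over target fractions.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(-(raw - base))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Grouped train/validation/blind split over identity clusters
#'
#' Whole clusters — hence every pair of a focal protein — are assigned to
#' exactly one subset. Cluster counts per subset follow the target ratios by
#' largest-remainder apportionment; cluster order is a seeded shuffle, so
#' the assignment is deterministic per seed.
#'
#' @param clusters data.frame from [clusterByIdentity()], or a named integer
#'   vector id -> cluster.
#' @param ratios Target fractions for (train, val, blind); must sum to 1
#'   (default 0.60 / 0.10 / 0.30).
#' @param seed Integer seed.
#' @return data.frame with columns `focal_parent_id`, `cluster`, `subset`.
#' @export
groupedSplit <- function(clusters, ratios = c(0.60, 0.10, 0.30), seed = 0L) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1", call. = FALSE)
  cl <- if (is.data.frame(clusters))
    stats::setNames(clusters$cluster, clusters$id) else clusters
  uniq <- unique(cl)
  if (length(uniq) < 3L)
    stop("data error: need at least as many clusters as subsets", call. = FALSE)
  shuffled <- withSeed(subSeed(seed, "grouped-split"), sample(uniq))
  sizes <- apportion(length(uniq), ratios)
  subsetOf <- rep(c("train", "val", "blind"), times = sizes)
  names(subsetOf) <- as.character(shuffled)
  data.frame(focal_parent_id = names(cl), cluster = unname(cl),
             subset = unname(subsetOf[as.character(cl)]),
             stringsAsFactors = FALSE)
}

#' Grouped k-fold cross-validation splits
#'
#' Clusters are dealt into k disjoint test folds of near-equal size (~20%
#' each at k = 5); within each fold the remaining clusters are split into
#' training and validation so the overall ratio is train:val:test =
#' 70:10:20. No focal protein ever crosses folds.
#'
#' @inheritParams groupedSplit
#' @param k Number of folds (default 5).
#' @param innerRatios Overall fractions for (train, val) (default 0.70 /
#'   0.10); rescaled to the non-test clusters of each fold.
#' @return data.frame with columns `focal_parent_id`, `cluster`, `fold`,
#'   `subset` — one row per focal id per fold.
#' @export
groupedKfold <- function(clusters, k = 5L, innerRatios = c(0.70, 0.10),
                         seed = 0L) {
  if (k < 2L) stop("configuration error: k must be >= 2", call. = FALSE)
  cl <- if (is.data.frame(clusters))
    stats::setNames(clusters$cluster, clusters$id) else clusters
  uniq <- unique(cl)
  if (length(uniq) < k)
    stop("data error: fewer clusters than folds", call. = FALSE)
  shuffled <- withSeed(subSeed(seed, "grouped-kfold"), sample(uniq))
  foldOf <- stats::setNames(rep(seq_len(k), length.out = length(uniq)),
                            as.character(shuffled))
  inner <- innerRatios / sum(innerRatios)
  out <- list()
  for (f in seq_len(k)) {
    testClusters <- as.character(shuffled[foldOf[as.character(shuffled)] == f])
    rest <- setdiff(as.character(shuffled), testClusters)
    sizes <- apportion(length(rest), inner)
    sub <- stats::setNames(rep(c("train", "val"), times = sizes), rest)
    sub[testClusters] <- "blind"
    out[[f]] <- data.frame(focal_parent_id = names(cl), cluster = unname(cl),
                           fold = f, subset = unname(sub[as.character(cl)]),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Classify a peptide as disordered from its secondary-structure string
#'
#' @param secondaryStructure Per-residue string over the three-state
#'   alphabet H (helix), E (strand), C (coil).
#' @param threshold Coil fraction at or above which the peptide is called
#'   disordered (default 75%, inclusive).
#' @return TRUE iff the coil fraction is `>= threshold` percent.
#' @examples
#' classifyDisorder("CCCCCCCCHH")  # 80% coil -> TRUE
#' @export
classifyDisorder <- function(secondaryStructure, threshold = 75) {
  if (!nzchar(secondaryStructure))
    stop("input error: empty secondary-structure string", call. = FALSE)
  chars <- strsplit(secondaryStructure, "")[[1L]]
  bad <- setdiff(unique(chars), c("H", "E", "C"))
  if (length(bad))
    stop("input error: characters outside {H,E,C}: ",
         paste(bad, collapse = ","), call. = FALSE)
  100 * mean(chars == "C") >= threshold
}
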