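# Residue-level evaluation: confusion tallies at a fixed cutoff,
# threshold-free AUROC / PRAUC, reconstruction of confusion counts from
# printed summary statistics, and the scrambled-partner control.
#
# Metrics are micro-averaged: residues are pooled across all pairs before
# tallying, matching dataset-level reporting for heavily imbalanced
# residue classification.

#' Confusion counts at a probability cutoff
#'
#' The positive call is inclusive: `p >= cutoff` predicts interface.
#'
#' @param probabilities Numeric vector (or
#'   [ResidueProbabilityTrack-class]).
#' @param labels 0/1 vector of the same length.
#' @param cutoff Probability cutoff (default 0.5).
#' @return A [ConfusionCounts-class].
#' @export
confusion <- function(probabilities, labels, cutoff = 0.5) {
  if (is(probabilities, "ResidueProbabilityTrack"))
    probabilities <- probabilities(probabilities)
  if (length(probabilities) != length(labels))
    stop("shape error: probabilities and labels differ in length", call. = FALSE)
  call_ <- probabilities >= cutoff
  y <- as.logical(labels)
  confusionCounts(TP = sum(call_ & y), FP = sum(call_ & !y),
                  FN = sum(!call_ & y), TN = sum(!call_ & !y),
                  cutoff = cutoff)
}

safeDiv <- function(num, den) if (den == 0) NA_real_ else num / den

#' Threshold metrics from confusion counts
#'
#' Accuracy, recall and precision in percent; F1 and MCC unitless. Metrics
#' with a degenerate (zero) denominator are reported as 0 and flagged in
#' `degenerate` so batch reports never crash.
#'
#' @param c A [ConfusionCounts-class].
#' @return List with `accuracy`, `recall`, `precision` (percent), `f1`,
#'   `mcc`, `support_positive`, `support_total`, `degenerate` (character
#'   vector of zero-denominator metrics).
#' @examples
#' metricsFromConfusion(confusionCounts(880, 899, 5420, 204020))
#' @export
metricsFromConfusion <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  ct <- counts(c)
  TP <- ct["TP"]; FP <- ct["FP"]; FN <- ct["FN"]; TN <- ct["TN"]
  total <- sum(ct)
  degenerate <- character(0)
  rec <- safeDiv(TP, TP + FN)
  if (is.na(rec)) { rec <- 0; degenerate <- c(degenerate, "recall") }
  prec <- safeDiv(TP, TP + FP)
  if (is.na(prec)) { prec <- 0; degenerate <- c(degenerate, "precision") }
  f1 <- if (prec + rec == 0) { degenerate <- c(degenerate, "f1"); 0 }
        else 2 * prec * rec / (prec + rec)
  mccDen <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mccDen == 0) { degenerate <- c(degenerate, "mcc"); 0 }
         else (TP * TN - FP * FN) / mccDen
  list(accuracy = unname(100 * (TP + TN) / total),
       recall = unname(100 * rec), precision = unname(100 * prec),
       f1 = unname(f1), mcc = unname(mcc),
       support_positive = unname(TP + FN), support_total = unname(total),
       degenerate = degenerate)
}

#' Reconstruct confusion counts from printed recall/precision
#'
#' Inverts the rounding pipeline of a published results table: given recall
#' and precision in percent plus the positive and total residue counts of
#' the dataset, reconstructs integer TP/FP/FN/TN (nearest-integer rounding
#' on TP then FP). This lets accuracy, F1 and MCC of a printed row be
#' recomputed and checked for internal consistency.
#'
#' @param recallPct,precisionPct Printed recall and precision in percent
#'   (both in (0, 100]).
#' @param positives Number of positive residues in the dataset.
#' @param total Total residues in the dataset.
#' @return A [ConfusionCounts-class].
#' @examples
#' reconstructConfusion(13.97, 49.47, 6300, 211219)
#' @export
reconstructConfusion <- function(recallPct, precisionPct, positives, total) {
  stopifnot(recallPct > 0, recallPct <= 100,
            precisionPct > 0, precisionPct <= 100, positives <= total)
  TP <- round(recallPct / 100 * positives)
  FP <- round(TP * (100 / precisionPct - 1))
  FN <- positives - TP
  TN <- total - TP - FP - FN
  if (min(TP, FP, FN, TN) < 0)
    stop("inconsistency error: reconstruction yields a negative count",
         call. = FALSE)
  confusionCounts(TP, FP, FN, TN)
}

#' Area under the ROC curve (rank statistic, ties counted half)
#'
#' Equivalent to the probability that a uniformly drawn positive outscores a
#' uniformly drawn negative, with ties contributing 1/2 (the Mann-Whitney
#' convention).
#'
#' @param probabilities Numeric score vector.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(probabilities, labels) {
  y <- as.logical(labels)
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0L || nNeg == 0L)
    stop("undefined-metric error: both classes must be present", call. = FALSE)
  r <- rank(probabilities, ties.method = "average")
  (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (stepwise over recall)
#'
#' Thresholds sweep the distinct scores from high to low; the area is the
#' sum over recall increments of the precision at each threshold (average
#' -precision-style step interpolation). Tied scores enter together.
#'
#' @inheritParams auroc
#' @return PRAUC in `[0, 1]`.
#' @export
prauc <- function(probabilities, labels) {
  y <- as.numeric(labels)
  nPos <- sum(y == 1)
  if (nPos == 0 || nPos == length(y))
    stop("undefined-metric error: both classes must be present", call. = FALSE)
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; y <- y[ord]
  grp <- cumsum(!duplicated(p))
  tpCum <- cumsum(y); nCum <- seq_along(y)
  lastOfGrp <- !duplicated(grp, fromLast = TRUE)
  tp <- tpCum[lastOfGrp]; n <- nCum[lastOfGrp]
  recall <- tp / nPos
  precision <- tp / n
  sum(diff(c(0, recall)) * precision)
}

#' Full metric report for pooled predictions
#'
#' @inheritParams confusion
#' @return List combining [metricsFromConfusion()] output with `auroc` and
#'   `prauc`.
#' @export
metricReport <- function(probabilities, labels, cutoff = 0.5) {
  if (is(probabilities, "ResidueProbabilityTrack"))
    probabilities <- probabilities(probabilities)
  m <- metricsFromConfusion(confusion(probabilities, labels, cutoff))
  m$auroc <- auroc(probabilities, labels)
  m$prauc <- prauc(probabilities, labels)
  m
}

#' Scramble a partner sequence, preserving composition
#'
#' Uniform seeded permutation of the residues — the scrambled-partner
#' control: evaluating the standard prediction path with scrambled partners
#' quantifies how much a model depends on partner identity rather than
#' composition.
#'
#' @param sequence Amino-acid string.
#' @param seed Integer seed.
#' @return Permuted string with the identical residue multiset.
#' @examples
#' scramblePartner("ACDEFGHIK", seed = 1)
#' @export
scramblePartner <- function(sequence, seed = 0L) {
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  chars <- strsplit(sequence, "")[[1L]]
  withSeed(subSeed(seed, "scramble"), paste(sample(chars), collapse = ""))
}

#' Write a metric report as TSV and JSON
#'
#' @param report List from [metricReport()] (or several, named by dataset
#'   tag).
#' @param pathPrefix Output prefix; `<prefix>.tsv` and `<prefix>.json` are
#'   written.
#' @return The two paths, invisibly.
#' @export
writeMetricReport <- function(report, pathPrefix) {
  if (!is.null(report$accuracy)) report <- list(dataset = report)
  rows <- do.call(rbind, lapply(names(report), function(tag) {
    r <- report[[tag]]
    data.frame(dataset = tag, accuracy = r$accuracy, recall = r$recall,
               precision = r$precision, f1 = r$f1, mcc = r$mcc,
               auroc = if (is.null(r$auroc)) NA else r$auroc,
               prauc = if (is.null(r$prauc)) NA else r$prauc)
  }))
  tsv <- paste0(pathPrefix, ".tsv"); js <- paste0(pathPrefix, ".json")
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
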