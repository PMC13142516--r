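# Prediction driver, checkpoints, and the partner-ensemble scan.

test_that("scan summaries match sort-based order statistics", {
  set.seed(12)
  tracks <- lapply(1:5, function(i)
    probabilityTrack("q", runif(30), paste0("p", i)))
  sc <- scanPartners(tracks, threshold = 0.10)
  M <- do.call(rbind, lapply(tracks, probabilities))
  for (pos in c(1, 7, 30)) {
    v <- sort(M[, pos])
    expect_equal(sc$median[pos], stats::median(v))
    expect_equal(sc$q1[pos], unname(stats::quantile(v, 0.25)))
    expect_equal(sc$q3[pos], unname(stats::quantile(v, 0.75)))
    expect_equal(sc$fraction_ge_threshold[pos], mean(M[, pos] >= 0.10))
  }
  expect_true(all(sc$q1 <= sc$median & sc$median <= sc$q3))

  # permutation invariance over partner order
  sc2 <- scanPartners(tracks[c(3, 1, 5, 2, 4)])
  expect_equal(sc2$median, sc$median)
  expect_equal(sc2$fraction_ge_threshold, sc$fraction_ge_threshold)
})

test_that("single partners and threshold boundaries behave as documented", {
  tr <- probabilityTrack("q", c(0.05, 0.10, 0.95), "p")
  sc <- scanPartners(list(tr))
  expect_equal(sc$median, probabilities(tr))
  expect_true(all(sc$fraction_ge_threshold %in% c(0, 1)))
  expect_equal(sc$fraction_ge_threshold, c(0, 1, 1))   # inclusive at 0.10

  sc3 <- scanPartners(list(c(0.05, 0.3), c(0.15, 0.3), c(0.25, 0.3)))
  expect_equal(sc3$fraction_ge_threshold[1], 2 / 3)
  expect_error(scanPartners(list()), "empty")
})

test_that("checkpoints round-trip parameters, config and tag", {
  cfg <- tinyConfig()
  p <- initModel(cfg, seed = 4)
  f <- withr::local_tempfile(fileext = ".ckpt")
  saveCheckpoint(p, f, "receptor_centric")
  back <- loadCheckpoint(f)
  expect_equal(back$modelTag, "receptor_centric")
  expect_equal(back$params$Wq, p$Wq)
  expect_equal(embedDim(back$config), 8L)
  EA <- randomEmbedding(3, 8, 1); EB <- randomEmbedding(4, 8, 2)
  expect_equal(probabilities(predictPair(EA, EB, back$params)),
               probabilities(predictPair(EA, EB, p)))
})

test_that("the prediction driver resolves pairs, errors on unknown IDs, and is deterministic", {
  dir <- withr::local_tempdir()
  ds <- generatePairDataset(3, seed = 6)
  writePairDataset(ds, dir)
  cfg <- modelConfig(embedDim = 16, numHeads = 2)
  ck <- file.path(dir, "model.ckpt")
  saveCheckpoint(initModel(cfg, seed = 1), ck)
  emb <- embedderSpec("synthetic", embedDim = 16, seed = 9)

  out1 <- file.path(dir, "tracks1.tsv")
  tracks <- runPredict(file.path(dir, "queries.fasta"),
                       file.path(dir, "partners.fasta"),
                       file.path(dir, "pairs.tsv"), ck, emb, out1)
  expect_length(tracks, 3)
  expect_equal(nResidues(tracks[[1]]), nchar(ds$pairs[[1]]$query))
  tab <- read.delim(out1)
  expect_equal(nrow(tab), sum(nchar(vapply(ds$pairs, `[[`, character(1), "query"))))
  expect_true(all(tab$probability >= 0 & tab$probability <= 1))

  out2 <- file.path(dir, "tracks2.tsv")
  runPredict(file.path(dir, "queries.fasta"), file.path(dir, "partners.fasta"),
             file.path(dir, "pairs.tsv"), ck, emb, out2)
  expect_identical(readLines(out1), readLines(out2))

  badPairs <- file.path(dir, "bad.tsv")
  write.table(data.frame(query_id = "XYZ", partner_id = "P0001"), badPairs,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(runPredict(file.path(dir, "queries.fasta"),
                          file.path(dir, "partners.fasta"), badPairs, ck, emb),
               "XYZ")

  wrongEmb <- embedderSpec("synthetic", embedDim = 8, seed = 9)
  expect_error(runPredict(file.path(dir, "queries.fasta"),
                          file.path(dir, "partners.fasta"),
                          file.path(dir, "pairs.tsv"), ck, wrongEmb),
               "incompatible")
})

test_that("long sequences route through chunked inference with consistent output", {
  dir <- withr::local_tempdir()
  set.seed(8)
  qs <- c(qlong = paste(sample(crossPPI:::AA_ALPHABET20, 50, TRUE), collapse = ""))
  ps <- c(p1 = paste(sample(crossPPI:::AA_ALPHABET20, 20, TRUE), collapse = ""))
  writeFastaSequences(qs, file.path(dir, "q.fasta"))
  writeFastaSequences(ps, file.path(dir, "p.fasta"))
  write.table(data.frame(query_id = "qlong", partner_id = "p1"),
              file.path(dir, "pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- modelConfig(embedDim = 8, numHeads = 2)
  ck <- file.path(dir, "m.ckpt")
  saveCheckpoint(initModel(cfg, seed = 2), ck)
  emb <- embedderSpec("synthetic", embedDim = 8, seed = 3)
  tr <- runPredict(file.path(dir, "q.fasta"), file.path(dir, "p.fasta"),
                   file.path(dir, "pairs.tsv"), ck, emb,
                   window = 32L, stride = 16L)
  expect_equal(nResidues(tr[[1]]), 50L)
  # same result as calling the chunked path directly
  EA <- embedSequence(qs[[1]], emb, "qlong")
  EB <- embedSequence(ps[[1]], emb, "p1")
  direct <- predictLongPair(EA, EB, loadCheckpoint(ck)$params,
                            window = 32L, stride = 16L)
  expect_equal(probabilities(tr[[1]]), probabilities(direct))
})

test_that("run manifests record versions, seed and input digests", {
  f <- withr::local_tempfile(fileext = ".json")
  inp <- withr::local_tempfile(fileext = ".txt")
  writeLines("hello", inp)
  writeRunManifest(f, seed = 42, inputs = inp, extra = list(mode = "test"))
  m <- jsonlite::fromJSON(f)
  expect_equal(m$seed, 42)
  expect_equal(m$package, "crossPPI")
  expect_equal(m$mode, "test")
  expect_true(nzchar(m$inputs[[1]]$md5))
})
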