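# Record filtering, identity clustering, grouped splits, disorder calls.

fakeRecords <- function() {
  data.frame(
    pdb_id = sprintf("%04d", 1:6),
    receptor_chain = "A", peptide_chain = "B",
    peptide_length = c(10, 10, 10, 10, 10, 35),
    receptor_parent_ids = c("P1", "P2;P3", "P4", "", "P5", "P6"),
    peptide_parent_ids = "L1",
    receptor_identity = c(100, 100, 89.9, 100, 95, 100),
    peptide_identity = 100,
    is_antibody_complex = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

test_that("record filtering applies each exclusion rule with its own tag", {
  fl <- filterRecords(fakeRecords(), "receptor")
  expect_equal(nrow(fl$kept), 1)
  expect_equal(fl$kept$focal_parent_id, "P1")
  expect_setequal(fl$rejected$reason,
                  c("multi-uniprot", "identity<90", "no-uniprot", "antibody",
                    "peptide>30"))
  # kept + rejected partition the input
  expect_equal(nrow(fl$kept) + nrow(fl$rejected), 6)

  # boundary: exactly 90% identity is kept
  rec <- fakeRecords()[1, ]
  rec$receptor_identity <- 90
  expect_equal(nrow(filterRecords(rec, "receptor")$kept), 1)
  rec$receptor_identity <- 89.999
  expect_equal(nrow(filterRecords(rec, "receptor")$rejected), 1)
})

test_that("the annotation reader validates required columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(fakeRecords(), f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(readComplexRecords(f)), 6)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(fakeRecords()[, -4], f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readComplexRecords(f2), "missing column")
})

test_that("greedy clustering follows the representative rule", {
  expect_equal(length(unique(
    clusterByIdentity(c(a = "ACDEFGHIKLMNP", b = "ACDEFGHIKLMNP"))$cluster)), 1)
  expect_equal(length(unique(
    clusterByIdentity(c(a = strrep("AC", 10), b = strrep("WY", 10)))$cluster)), 2)

  # A~B similar, C unrelated (no positive-scoring local alignment against
  # either): greedy representative rule gives {A,B}, {C}
  A <- paste0("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  B <- paste0("MKTAYIAKQRQISFVKSHFSSSSSSSSSSSSSS")   # shares a long A prefix
  C <- strrep("P", 30)
  cl <- clusterByIdentity(c(A = A, B = B, C = C))
  expect_equal(cl$cluster[cl$id == "A"], cl$cluster[cl$id == "B"])
  expect_false(cl$cluster[cl$id == "C"] == cl$cluster[cl$id == "A"])

  # re-clustering representatives yields singletons
  reps <- unique(cl$representative)
  seqs <- c(A = A, B = B, C = C)[reps]
  cl2 <- clusterByIdentity(seqs)
  expect_equal(length(unique(cl2$cluster)), length(reps))
  expect_error(clusterByIdentity(character(0)), "no sequences")
})

test_that("grouped splits apportion clusters 6/1/3 and keep clusters intact", {
  cl <- stats::setNames(1:10, paste0("p", 1:10))
  sp <- groupedSplit(cl, seed = 1)
  expect_equal(unname(table(sp$subset)[c("train", "val", "blind")]),
               c(6L, 1L, 3L), ignore_attr = TRUE)

  # one cluster of five focal proteins stays together
  cl5 <- stats::setNames(c(1, 1, 1, 1, 1, 2, 3, 4), paste0("q", 1:8))
  sp5 <- groupedSplit(cl5, seed = 3)
  expect_equal(length(unique(sp5$subset[sp5$cluster == 1])), 1)

  expect_identical(groupedSplit(cl, seed = 7), groupedSplit(cl, seed = 7))
  expect_error(groupedSplit(stats::setNames(c(1, 1), c("a", "b"))), "at least")
})

test_that("grouped k-fold forms disjoint complete test folds with 7/1 inner splits", {
  cl <- stats::setNames(1:10, paste0("p", 1:10))
  kf <- groupedKfold(cl, k = 5, seed = 2)
  for (f in 1:5) {
    sub <- kf[kf$fold == f, ]
    expect_equal(sum(sub$subset == "blind"), 2)
    expect_equal(sum(sub$subset == "train"), 7)
    expect_equal(sum(sub$subset == "val"), 1)
  }
  # test folds partition the clusters
  blind <- lapply(1:5, function(f)
    sort(kf$cluster[kf$fold == f & kf$subset == "blind"]))
  expect_equal(sort(unlist(blind)), 1:10)
  expect_equal(anyDuplicated(unlist(blind)), 0)

  # a focal protein with several partners appears in exactly one test fold
  cl2 <- stats::setNames(c(1, 1, 1, 2:8), paste0("x", 1:10))
  kf2 <- groupedKfold(cl2, k = 5, seed = 4)
  foldsOfX1 <- unique(kf2$fold[kf2$focal_parent_id == "x1" & kf2$subset == "blind"])
  expect_equal(length(foldsOfX1), 1)
  expect_error(groupedKfold(cl, k = 1), "k must be")
  expect_error(groupedKfold(stats::setNames(1:3, letters[1:3]), k = 5), "fewer clusters")
})

test_that("disorder is called from the coil fraction with an inclusive threshold", {
  expect_true(classifyDisorder("CCCCCCCCHH"))
  expect_true(classifyDisorder("CCCH"))                 # exactly 75%
  expect_false(classifyDisorder("HHHH"))
  expect_false(classifyDisorder("CCHH"))
  expect_error(classifyDisorder(""), "empty")
  expect_error(classifyDisorder("CCXH"), "outside")
})
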