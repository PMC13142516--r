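# Residue-level evaluation: confusion tallies, printed-table reconstruction,
# rank-based curves, and the scrambled-partner control.

test_that("confusion tallies use an inclusive cutoff and conserve counts", {
  c1 <- confusion(c(0.6, 0.4), c(1, 0))
  expect_equal(unname(counts(c1)), c(1, 0, 0, 1))
  # a probability exactly at the cutoff is a positive call
  c2 <- confusion(c(0.5), c(0))
  expect_equal(unname(counts(c2)["FP"]), 1)

  set.seed(1)
  p <- runif(1000); y <- rbinom(1000, 1, 0.1)
  expect_equal(sum(counts(confusion(p, y))), 1000)
  expect_error(confusion(c(0.1), c(1, 0)), "shape")
})

test_that("threshold metrics reproduce published receptor-blind-set numbers", {
  m <- metricsFromConfusion(confusionCounts(880, 899, 5420, 204020))
  expect_equal(m$accuracy, 97.01, tolerance = 1e-4)
  expect_equal(m$mcc, 0.252, tolerance = 2e-3)   # printed to three decimals
  expect_equal(m$f1, 0.218, tolerance = 2e-3)

  perfect <- metricsFromConfusion(confusionCounts(10, 0, 0, 90))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)

  allNeg <- metricsFromConfusion(confusionCounts(0, 0, 10, 90))
  expect_equal(allNeg$recall, 0)
  expect_equal(allNeg$mcc, 0)
  expect_true(all(c("precision", "mcc") %in% allNeg$degenerate))
})

test_that("confusion reconstruction inverts printed recall and precision", {
  c1 <- reconstructConfusion(13.97, 49.47, 6300, 211219)
  expect_equal(unname(counts(c1)), c(880, 899, 5420, 204020))
  c2 <- reconstructConfusion(100, 100, 10, 100)
  expect_equal(unname(counts(c2)), c(10, 0, 0, 90))
  c3 <- reconstructConfusion(16.15, 46.95, 5666, 343673)
  expect_equal(unname(counts(c3)[c("TP", "FP")]), c(915, 1034))
  expect_error(reconstructConfusion(100, 1, 99, 100), "negative")
})

test_that("AUROC equals exhaustive pair ordering, including ties", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)

  set.seed(23)
  for (L in 2:8) {
    for (rep in 1:20) {
      y <- rbinom(L, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- sample(seq(0, 1, 0.25), L, replace = TRUE)   # deliberate ties
      expect_equal(auroc(s, y), pairOrderAuroc(s, y), tolerance = 1e-12)
    }
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUROC and PRAUC agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (rep in 1:5) {
    y <- rbinom(300, 1, 0.15)
    s <- runif(300) + 0.5 * y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
    expect_equal(auroc(s, y), ref, tolerance = 1e-9)
  }
})

test_that("PRAUC uses stepwise interpolation over recall", {
  expect_equal(prauc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  # hand case: scores 0.9(+), 0.8(-), 0.7(+): steps at recall 1/2 (prec 1)
  # and recall 1 (prec 2/3)
  expect_equal(prauc(c(0.9, 0.8, 0.7), c(1, 0, 1)), 0.5 * 1 + 0.5 * (2 / 3))
  # random predictor's PRAUC is near the base rate
  set.seed(4)
  y <- rbinom(4000, 1, 0.2)
  expect_equal(prauc(runif(4000), y), 0.2, tolerance = 0.05)
})

test_that("label swap with complemented scores preserves AUROC and swaps recall/specificity", {
  set.seed(9)
  y <- rbinom(200, 1, 0.3)
  s <- runif(200)
  expect_equal(auroc(s, y), auroc(1 - s, 1 - y), tolerance = 1e-12)
  m <- metricsFromConfusion(confusion(s, y, cutoff = 0.5))
  # complementing scores turns p >= 0.5 into p <= 0.5; use a strict mirror
  sw <- counts(confusion(s, y, 0.5))
  spec <- 100 * sw["TN"] / (sw["TN"] + sw["FP"])
  m2 <- metricsFromConfusion(confusionCounts(sw["TN"], sw["FN"], sw["FP"], sw["TP"]))
  expect_equal(m2$recall, unname(spec))
})

test_that("partner scrambling preserves composition and is a seeded permutation", {
  expect_equal(scramblePartner("AAAA", 1), "AAAA")
  for (seed in 1:20) {
    s <- paste(sample(crossPPI:::AA_ALPHABET20, 15, replace = TRUE), collapse = "")
    sc <- scramblePartner(s, seed)
    expect_equal(sort(strsplit(sc, "")[[1]]), sort(strsplit(s, "")[[1]]))
    expect_identical(sc, scramblePartner(s, seed))
  }
  # near-uniform position occupancy across seeds
  s <- "ACDEFGHIKL"
  firsts <- vapply(1:500, function(sd) substr(scramblePartner(s, sd), 1, 1),
                   character(1))
  tab <- table(factor(firsts, levels = strsplit(s, "")[[1]]))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})
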