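# Cross-attention model: construction, forward-pass semantics, parameter
# accounting and weight inspection.

test_that("initialisation is deterministic, shaped, and rejects bad configs", {
  cfg <- tinyConfig(d = 8L, heads = 2L)
  p1 <- initModel(cfg, seed = 1)
  p2 <- initModel(cfg, seed = 1)
  expect_identical(p1[paramNamesForTest()], p2[paramNamesForTest()])
  expect_equal(dim(p1$Wq), c(8L, 8L))
  expect_equal(dim(p1$mlpW1), c(8L, 8L))
  expect_false(identical(p1$Wq, initModel(cfg, seed = 2)$Wq))

  expect_equal(headDim(modelConfig(embedDim = 1280, numHeads = 16)), 80L)
  expect_error(modelConfig(embedDim = 10, numHeads = 3), "divisible")
})

test_that("attention rows are simplex weights and collapse to uniform for zero Q/K", {
  cfg <- tinyConfig()
  p <- initModel(cfg, seed = 3)
  EA <- randomEmbedding(5, 8, 11, "a")
  EB <- randomEmbedding(7, 8, 12, "b")
  ca <- crossAttention(EA, EB, p, cfg)
  for (A in ca$attention) {
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-6)
  }
  p0 <- p; p0$Wq[] <- 0; p0$bq[] <- 0; p0$Wk[] <- 0; p0$bk[] <- 0
  ca0 <- crossAttention(EA, EB, p0, cfg)
  for (A in ca0$attention)
    expect_equal(A, matrix(1 / 7, 5, 7), tolerance = 1e-12)

  expect_error(crossAttention(randomEmbedding(3, 4, 1), EB, p, cfg), "shape")
})

test_that("forward pass matches the dense-loop oracle on small random cases", {
  set.seed(42)
  for (rep in 1:12) {
    d <- sample(c(4L, 6L, 8L), 1)
    heads <- sample(c(1L, 2L), 1)
    cfg <- tinyConfig(d = d, heads = heads, mlpHidden = sample(3:8, 1))
    p <- initModel(cfg, seed = rep)
    LA <- sample(1:5, 1); LB <- sample(1:5, 1)
    X <- matrix(rnorm(LA * d), LA, d)
    Y <- matrix(rnorm(LB * d), LB, d)
    got <- probabilities(predictPair(embeddingMatrix("a", X, "synthetic"),
                                     embeddingMatrix("b", Y, "synthetic"), p, cfg))
    expect_equal(got, denseForwardOracle(X, Y, p, cfg), tolerance = 1e-6)
  }
})

test_that("all-zero parameters give probability one half everywhere", {
  cfg <- tinyConfig()
  p <- initModel(cfg, seed = 1)
  for (nm in paramNamesForTest()) p[[nm]][] <- 0
  out <- probabilities(predictPair(randomEmbedding(4, 8, 1), randomEmbedding(3, 8, 2), p, cfg))
  expect_equal(out, rep(0.5, 4))
})

test_that("output is invariant to partner row order and equivariant to query row order", {
  cfg <- tinyConfig()
  p <- initModel(cfg, seed = 5)
  X <- matrix(rnorm(6 * 8), 6, 8)
  Y <- matrix(rnorm(9 * 8), 9, 8)
  base <- probabilities(predictPair(embeddingMatrix("a", X, "synthetic"),
                                    embeddingMatrix("b", Y, "synthetic"), p, cfg))
  for (rep in 1:5) {
    permB <- sample(9)
    permA <- sample(6)
    permPartner <- probabilities(predictPair(
      embeddingMatrix("a", X, "synthetic"),
      embeddingMatrix("b", Y[permB, ], "synthetic"), p, cfg))
    expect_equal(permPartner, base, tolerance = 1e-12)
    permQuery <- probabilities(predictPair(
      embeddingMatrix("a", X[permA, ], "synthetic"),
      embeddingMatrix("b", Y, "synthetic"), p, cfg))
    expect_equal(permQuery, base[permA], tolerance = 1e-12)
  }
})

test_that("parameter accounting matches hand arithmetic and the instantiated model", {
  ct <- countParameters(tinyConfig(d = 8L, heads = 2L, mlpHidden = 8L))
  expect_equal(unname(ct["attention_block"]), 304)
  expect_equal(unname(ct["mlp_block"]), 81)
  expect_equal(unname(ct["total"]), 385)

  set.seed(7)
  for (rep in 1:5) {
    heads <- sample(c(1L, 2L, 4L), 1)
    d <- heads * sample(2:6, 1)
    cfg <- tinyConfig(d = d, heads = heads, mlpHidden = sample(2:9, 1))
    expect_equal(unname(countParameters(cfg)["total"]),
                 countInstantiatedForTest(initModel(cfg, seed = rep)))
  }
})

test_that("per-head norms match brute-force sums of squares", {
  cfg <- tinyConfig(d = 8L, heads = 2L)
  p <- initModel(cfg, seed = 9)

  z <- p; for (nm in c("Wq", "Wk", "Wv")) z[[nm]][] <- 0
  expect_true(all(perHeadNorms(z, cfg)$norms$L2_norm == 0))

  one <- initModel(tinyConfig(d = 4L, heads = 1L), seed = 1)
  one$Wq <- diag(4)
  nQ <- perHeadNorms(one)$norms
  expect_equal(nQ$L2_norm[nQ$projection == "Q"], 2)

  got <- perHeadNorms(p, cfg)$norms
  for (r in seq_len(nrow(got))) {
    W <- switch(as.character(got$projection[r]), Q = p$Wq, K = p$Wk, V = p$Wv)
    idx <- ((got$head[r] - 1) * 4 + 1):(got$head[r] * 4)
    brute <- 0
    for (i in 1:8) for (j in idx) brute <- brute + W[i, j]^2
    expect_equal(got$L2_norm[r], sqrt(brute), tolerance = 1e-9)
  }
})
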