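# Overlapping-window chunking and max-pool aggregation.

test_that("chunk plans follow the stride rule with an end-aligned final chunk", {
  expect_equal(unname(planChunks(1000)$chunks), cbind(0L, 1000L))
  expect_equal(unname(planChunks(2048)$chunks),
               cbind(c(0L, 512L, 1024L, 1026L), c(1022L, 1534L, 2046L, 2048L)))
  expect_equal(unname(planChunks(1022)$chunks), cbind(0L, 1022L))
  expect_error(planChunks(100, window = 16, stride = 20), "stride")

  # coverage property over random lengths
  set.seed(5)
  for (rep in 1:20) {
    L <- sample(1:500, 1)
    w <- sample(10:60, 1)
    s <- sample(seq_len(w), 1)
    ch <- planChunks(L, w, s)$chunks
    covered <- logical(L)
    for (r in seq_len(nrow(ch))) covered[(ch[r, 1] + 1):ch[r, 2]] <- TRUE
    expect_true(all(covered))
    expect_true(all(ch[, 2] - ch[, 1] <= w))
    expect_equal(unname(ch[nrow(ch), 2]), L)
  }
})

test_that("max aggregation takes the positionwise maximum and flags gaps", {
  expect_equal(
    aggregateMax(list(list(interval = c(0, 2), values = c(0.3, 0.1)),
                      list(interval = c(0, 2), values = c(0.7, 0.05))), 2),
    c(0.7, 0.1))
  v <- runif(5)
  expect_equal(aggregateMax(list(list(interval = c(0, 5), values = v)), 5), v)

  tracks <- list(list(interval = c(0, 3), values = c(0.1, 0.2, 0.3)),
                 list(interval = c(2, 5), values = c(0.9, 0.1, 0.2)),
                 list(interval = c(1, 6), values = c(0.5, 0.05, 0.6, 0.0, 0.4)))
  got <- aggregateMax(tracks, 6)
  brute <- sapply(1:6, function(pos) {
    vals <- c()
    for (tr in tracks) {
      iv <- tr$interval
      if (pos > iv[1] && pos <= iv[2]) vals <- c(vals, tr$values[pos - iv[1]])
    }
    max(vals)
  })
  expect_equal(got, brute)
  expect_error(aggregateMax(list(list(interval = c(0, 2), values = c(0.1, 0.2))), 3),
               "coverage")
})

test_that("chunked prediction reduces to the direct path within one window", {
  cfg <- tinyConfig()
  p <- initModel(cfg, seed = 2)
  for (rep in 1:100) {
    set.seed(rep + 300)
    EA <- randomEmbedding(sample(1:40, 1), 8, rep, "a")
    EB <- randomEmbedding(sample(1:40, 1), 8, rep + 1000, "b")
    expect_identical(
      probabilities(predictLongPair(EA, EB, p, cfg, window = 64, stride = 32)),
      probabilities(predictPair(EA, EB, p, cfg)))
  }
})

test_that("chunked prediction equals the brute-force max over all chunk pairs", {
  cfg <- tinyConfig(d = 4L, heads = 1L)
  p <- initModel(cfg, seed = 6)
  EA <- randomEmbedding(30, 4, 41, "a")
  EB <- randomEmbedding(30, 4, 42, "b")
  got <- probabilities(predictLongPair(EA, EB, p, cfg, window = 16, stride = 8))

  planA <- planChunks(30, 16, 8)$chunks
  planB <- planChunks(30, 16, 8)$chunks
  brute <- rep(-Inf, 30)
  for (i in seq_len(nrow(planA))) {
    qa <- (planA[i, 1] + 1):planA[i, 2]
    for (j in seq_len(nrow(planB))) {
      qb <- (planB[j, 1] + 1):planB[j, 2]
      sub <- probabilities(predictPair(
        embeddingMatrix("a", embValues(EA)[qa, , drop = FALSE], "synthetic"),
        embeddingMatrix("b", embValues(EB)[qb, , drop = FALSE], "synthetic"),
        p, cfg))
      brute[qa] <- pmax(brute[qa], sub)
    }
  }
  expect_equal(got, brute, tolerance = 1e-12)

  # duplicating the partner as two identical chunks changes nothing
  EB2 <- embeddingMatrix("b", rbind(embValues(EB), embValues(EB))[1:30, ], "synthetic")
  expect_equal(got, probabilities(predictLongPair(EA, EB, p, cfg, 16, 8)))
})

test_that("adding a chunk pair never decreases any position's probability", {
  cfg <- tinyConfig(d = 4L, heads = 1L)
  p <- initModel(cfg, seed = 13)
  EA <- randomEmbedding(30, 4, 51, "a")
  EB <- randomEmbedding(25, 4, 52, "b")
  narrow <- probabilities(predictLongPair(EA, EB, p, cfg, window = 20, stride = 20))
  # a finer stride adds chunk pairs; max pooling is monotone in added tracks
  fine <- probabilities(predictLongPair(EA, EB, p, cfg, window = 20, stride = 5))
  expect_true(all(fine >= narrow - 1e-12))
})
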