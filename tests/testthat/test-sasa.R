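# Shrake-Rupley SASA, RSA normalisation, and delta-RSA interface labeling.

singleAtomChain <- function(xyz = c(0, 0, 0), r = 1.7, id = "A", n = 1) {
  coords <- matrix(xyz, n, 3, byrow = TRUE)
  chainStructure(id,
    residues = data.frame(resNo = seq_len(n), resName = "ALA"),
    atoms = data.frame(element = "C", resIdx = seq_len(n),
                       x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       radius = r))
}

test_that("isolated and well-separated spheres match the closed-form area", {
  s <- computeSasa(singleAtomChain())$A
  expect_equal(s, 4 * pi * 3.1^2, tolerance = 1e-3)   # within 0.1%

  far <- chainStructure("A",
    data.frame(resNo = 1:2, resName = "ALA"),
    data.frame(element = "C", resIdx = 1:2, x = c(0, 100), y = 0, z = 0,
               radius = 1.7))
  expect_equal(sum(computeSasa(far)$A), 2 * 4 * pi * 3.1^2, tolerance = 1e-6)
  expect_error(computeSasa(list()), "atoms")
})

test_that("two overlapping spheres match the spherical-cap formula within 2%", {
  for (D in c(2.0, 3.0, 4.5)) {
    pair <- chainStructure("A",
      data.frame(resNo = 1:2, resName = "ALA"),
      data.frame(element = "C", resIdx = 1:2, x = c(0, D), y = 0, z = 0,
                 radius = 1.7))
    est <- computeSasa(pair)$A
    R <- 1.7 + 1.4
    h <- R - D / 2                       # equal radii: cap height
    analytic <- 4 * pi * R^2 - 2 * pi * R * h
    expect_equal(est[1], analytic, tolerance = 0.02)
    expect_equal(est[2], analytic, tolerance = 0.02)
  }
})

test_that("RSA normalises by residue-type maxima with a generic fallback", {
  expect_equal(residueRsa(c(129.0), c("ALA")), 100)
  expect_equal(residueRsa(c(0), c("TRP")), 0)
  custom <- c(ALA = 109.0, UNK = 200)
  expect_equal(residueRsa(c(54.5), c("ALA"), custom), 50)
  expect_warning(got <- residueRsa(c(100), c("ZZZ")), "UNK")
  expect_equal(got, 100 * 100 / 203.0)
  expect_equal(residueRsa(c(250), c("ALA"), cap = TRUE), 100)
})

test_that("delta-RSA labels exactly the constructed contacts and nothing else", {
  toy <- generateToyComplex(10, 4, c(3, 7), seed = 1)
  res <- deltaRsaLabels(toy, "A")
  expect_equal(res$labels, as.integer(seq_len(10) %in% c(3, 7)))

  # verified by direct SASA differencing
  sasaC <- computeSasa(toy)$A
  sasaI <- computeSasa(toy$A)$A
  delta <- residueRsa(sasaI, rep("ALA", 10)) - residueRsa(sasaC, rep("ALA", 10))
  expect_equal(res$deltaRsa, delta)
  expect_true(all(delta >= 0))                        # separation monotonicity

  # single-chain self-complex: nothing changes on separation
  self <- deltaRsaLabels(list(toy$A), "A")
  expect_equal(sum(self$labels), 0)
  expect_equal(self$deltaRsa, rep(0, 10))

  # a residue exactly at the threshold is not labeled (strict inequality)
  d3 <- res$deltaRsa[3]
  atThresh <- deltaRsaLabels(toy, "A", threshold = d3)
  expect_equal(atThresh$labels[3], 0L)
  expect_error(deltaRsaLabels(toy, "Z"), "not present")
})

test_that("SASA is additive for chains at least 50 A apart", {
  toy <- generateToyComplex(5, 3, integer(0), seed = 2)
  both <- computeSasa(list(toy$A, toy$B))
  expect_equal(sum(both$A) + sum(both$B),
               sum(computeSasa(toy$A)$A) + sum(computeSasa(toy$B)$B),
               tolerance = 1e-9)
})

test_that("toy complexes survive a PDB round trip with identical labels", {
  toy <- generateToyComplex(8, 3, c(2, 5), seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeChainsPdb(toy, f)
  back <- readChains(f)
  expect_setequal(names(back), c("A", "B"))
  expect_equal(nResidues(back$A), 8)
  expect_equal(deltaRsaLabels(back, "A")$labels,
               deltaRsaLabels(toy, "A")$labels)
  expect_equal(chainSequence(back$A), strrep("A", 8))
})
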