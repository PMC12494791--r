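test_that("graph generation is a pure function of its seed", {
  g1 <- randomMolecularGraph(50, "tree", seed = 7)
  g2 <- randomMolecularGraph(50, "tree", seed = 7)
  expect_identical(g1@edges, g2@edges)
  g3 <- randomMolecularGraph(50, "tree", seed = 8)
  expect_false(identical(g1@edges, g3@edges))
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(randomMolecularGraph(20, "unicyclic", seed = 3))
  expect_identical(runif(1), before)
})

test_that("generated graphs satisfy their topology and degree contracts", {
  for (s in 1:50) {
    topo <- c("tree", "unicyclic", "connected")[1 + s %% 3]
    g <- randomMolecularGraph(c(5, 40), topo, seed = s)
    n <- numVertices(g)
    expect_true(isConnected(g))
    expect_lte(max(degreeSequence(g)), 4L)
    if (topo == "tree") expect_identical(numEdges(g), n - 1L)
    if (topo == "unicyclic") expect_identical(numEdges(g), n)
    if (topo == "connected") expect_gte(numEdges(g), n - 1L)
  }
  expect_equal(numEdges(randomMolecularGraph(2, "tree", seed = 1)), 1L)
  expect_error(randomMolecularGraph(3, "tree", maxDegree = 1, seed = 1),
               "infeasible")
  expect_error(randomMolecularGraph(1, "tree", seed = 1), "at least 2")
})

test_that("random symbolic partitions are realizable and deterministic", {
  rp1 <- randomSymbolicPartition(seed = 42)
  rp2 <- randomSymbolicPartition(seed = 42)
  expect_equal(partitionClasses(rp1$partition), partitionClasses(rp2$partition))
  for (s in c(1, 7, 19, 101)) {
    rp <- randomSymbolicPartition(seed = s)
    sp <- rp$partition
    # passes the handshake validator for n = 1..20
    expect_silent(degreeConsistency(sp))
    # total frequency linear with positive slope
    expect_gt(coef(totalEdges(sp))[["a"]], 0)
    # the generating template realizes the partition
    for (n in c(1, 3)) {
      got <- partitionClasses(edgePartition(assembleChain(rp$template, n)))
      want <- partitionClasses(evaluatePartition(sp, n))
      expect_equal(got$count, want$count)
    }
    # cross-module: entropy closed form agrees with direct evaluation
    for (nm in c("M1", "ABC")) {
      d <- builtinIndex(nm)
      ecf <- entropyClosedForm(sp, d)
      direct <- vapply(1:10, function(n)
        entropyValue(evaluatePartition(sp, n), d), 0)
      expect_equal(evaluateAt(ecf, 1:10), direct, tolerance = 1e-9)
    }
  }
})

test_that("noisy log series honour sigma = 0 and seeding", {
  d0 <- noisyLogSeries(1.5, -2, 0, 20, seed = 3)
  fit <- fitLogModel(d0$x, d0$y)
  expect_equal(coef(fit), c(a = 1.5, b = -2), tolerance = 1e-10)
  expect_equal(fit@R2, 1)
  dA <- noisyLogSeries(0.8, 0.3, 0.01, 50, seed = 9)
  dB <- noisyLogSeries(0.8, 0.3, 0.01, 50, seed = 9)
  expect_identical(dA, dB)
  expect_error(noisyLogSeries(1, 0, -0.1, 10, seed = 1), "sigma")
  expect_error(noisyLogSeries(1, 0, 0.1, 2, seed = 1), ">= 3")
})
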