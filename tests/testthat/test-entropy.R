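test_that("entropy reproduces frozen chain values and closed-form limits", {
  pe1 <- evaluatePartition(builtinPartition("polyester"), 1)
  expect_equal(entropyValue(pe1, builtinIndex("M1")), 3.0696, tolerance = 1e-4)
  expect_equal(entropyValue(pe1, builtinIndex("ReZG1")), 3.0382, tolerance = 1e-4)
  # uniform weights attain ln m
  expect_equal(entropyValue(cycleGraph(5), builtinIndex("M1")), log(5))
  expect_equal(entropyValue(cycleGraph(5), builtinIndex("GA")), log(5))
  # a single edge has zero entropy under any positive weight
  expect_equal(entropyValue(pathGraph(2), builtinIndex("M2")), 0)
})

test_that("entropy errors for a non-positive total index", {
  single11 <- EdgePartition(lo = 1, hi = 1, count = 1)
  expect_error(entropyValue(single11, builtinIndex("ABC")), "non-positive")
})

test_that("zero-weight classes contribute nothing (0 ln 0 = 0)", {
  # (1,1) edges have ABC weight 0; mixed with (3,3) edges TI stays positive
  mix <- EdgePartition(lo = c(1, 3), hi = c(1, 3), count = c(2, 3))
  w33 <- builtinWeightFns$ABC(3, 3)
  expect_equal(entropyValue(mix, builtinIndex("ABC")),
               oracleEntropy(c(0, 0, rep(w33, 3))))
})

test_that("entropy is bounded by ln m and matches the probability-form oracle", {
  for (s in 1:60) {
    g <- randomMolecularGraph(c(5, 30), c("tree", "unicyclic", "connected")[1 + s %% 3],
                              seed = 1000 + s)
    p <- edgePartition(g)
    m <- edgeCount(p)
    for (nm in c("M1", "M2", "ReZG1", "ReZG2", "ReZG3", "GA")) {
      d <- builtinIndex(nm)
      ent <- entropyValue(p, d)
      expect_gte(ent, 0)
      expect_lte(ent, log(m) + 1e-12)
      # grouped computation equals the ungrouped per-edge probability form
      expect_equal(ent, oracleEntropy(edgeWeights(g, builtinWeightFns[[nm]])),
                   tolerance = 1e-12)
    }
  }
})

test_that("entropy equals ln m exactly when all edge weights are equal", {
  for (n in c(4, 7, 11)) {
    expect_equal(entropyValue(cycleGraph(n), builtinIndex("M2")), log(n),
                 tolerance = 1e-12)
  }
  # and is strictly below ln m when weights differ
  g <- assembleChain(polymerTemplate("polyester"), 1)
  expect_lt(entropyValue(g, builtinIndex("M1")), log(numEdges(g)))
})

test_that("entropy closed forms agree with direct evaluation over n = 1..20", {
  for (pm in c("polyester", "polycarbonate")) {
    sp <- builtinPartition(pm)
    for (nm in builtinIndexNames()) {
      d <- builtinIndex(nm)
      ecf <- entropyClosedForm(sp, d)
      direct <- vapply(1:20, function(n)
        entropyValue(evaluatePartition(sp, n), d), 0)
      expect_equal(evaluateAt(ecf, 1:20), direct, tolerance = 1e-9)
    }
  }
})

test_that("verified weighted log-sum coefficients reproduce to print precision", {
  pe <- builtinPartition("polyester")
  pc <- builtinPartition("polycarbonate")
  sOf <- function(sp, nm) coef(entropyClosedForm(sp, builtinIndex(nm))@logSum)
  expect_equal(sOf(pe, "M1"), c(a = 205.6953, b = -15.7033), tolerance = 1e-4)
  expect_equal(sOf(pe, "M2"), c(a = 299.2895, b = -32.7749), tolerance = 1e-4)
  expect_equal(sOf(pe, "ReZG2"), c(a = 5.4480, b = -1.2248), tolerance = 1e-4)
  expect_equal(sOf(pc, "M2"), c(a = 413.856, b = -25.3202), tolerance = 5e-4)
  expect_equal(sOf(pc, "ReZG2"), c(a = 7.8702, b = -0.9267), tolerance = 1e-4)
  # ReZG1 entropies in the form ln(I n) + c + d/n
  sPe <- sOf(pe, "ReZG1")
  expect_equal(unname(-sPe / 22), c(-0.00785, -0.04498), tolerance = 1e-4)
  sPc <- sOf(pc, "ReZG1")
  expect_equal(unname(-sPc / 29), c(0.01958, -0.03669), tolerance = 1e-4)
})

test_that("entropy series match the reported chain values", {
  pe <- entropySeries(builtinPartition("polyester"), builtinIndex("M1"), 1:10)
  expect_equal(pe$entropy,
               c(3.0696, 3.7872, 4.2007, 4.4924, 4.7179,
                 4.9018, 5.0571, 5.1915, 5.3099, 5.4158),
               tolerance = 1e-4)
  pc <- builtinPartition("polycarbonate")
  expect_equal(entropySeries(pc, builtinIndex("ABC"), 1)$entropy, 3.3946,
               tolerance = 1e-4)
  expect_equal(entropySeries(pc, builtinIndex("ReZG1"), 1)$entropy, 3.3502,
               tolerance = 1e-4)
})

test_that("a single-class partition family has entropy ln of its edge count", {
  sp <- SymbolicPartition(lo = 2, hi = 2, a = 5, b = 0)   # {(2,2): 5n}
  ecf <- entropyClosedForm(sp, builtinIndex("M1"))
  expect_equal(evaluateAt(ecf, 1:6), log(5 * (1:6)), tolerance = 1e-12)
})
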