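test_that("built-in weights follow their definitions", {
  expect_equal(builtinIndex("M1")@weight(3, 3), 6)
  expect_equal(builtinIndex("M2")@weight(2, 4), 8)
  expect_equal(builtinIndex("ABC")@weight(1, 1), 0)
  for (d in 1:6) expect_equal(builtinIndex("GA")@weight(d, d), 1)
  expect_equal(builtinIndex("ReZG3")@weight(2, 3), 30)
  expect_error(builtinIndex("Wiener"), "registry")
})

test_that("custom index registration validates symmetry and sign", {
  h <- IndexDefinition("harmonic", function(a, b) 2 / (a + b),
                       ratWeight = function(a, b) c(2, a + b))
  expect_equal(indexValue(evaluatePartition(builtinPartition("polyester"), 1), h),
               1 * 2 / 3 + 5 * 2 / 4 + 5 * 2 / 5 + 2 * 2 / 5 + 1 * 2 / 6 +
                 7 * 2 / 6 + 1 * 2 / 8)
  expect_error(IndexDefinition("diff", function(a, b) a - b), "symmetric|negative")
})

test_that("index values reproduce frozen chain values", {
  pe1 <- evaluatePartition(builtinPartition("polyester"), 1)
  pc2 <- evaluatePartition(builtinPartition("polycarbonate"), 2)
  expect_identical(indexValue(pe1, builtinIndex("M1")), 114)
  expect_identical(indexValue(pe1, builtinIndex("M2")), 136)
  expect_identical(indexValue(pc2, builtinIndex("M2")), 398)
  # rational index values are exact, not approximately integer
  expect_identical(indexValue(pe1, builtinIndex("ReZG1")), 22)
  expect_identical(indexValue(pe1, builtinIndex("ReZG2")), 493 / 20)  # 24.65
})

test_that("graph and partition summation routes agree with the brute-force oracle", {
  seeds <- 1:200
  topos <- c("tree", "unicyclic", "connected")
  for (s in seeds) {
    g <- randomMolecularGraph(c(6, 25), topos[1 + s %% 3], seed = s)
    p <- edgePartition(g)
    for (nm in builtinIndexNames()) {
      d <- builtinIndex(nm)
      vg <- indexValue(g, d)
      vp <- indexValue(p, d)
      vo <- oracleGraphIndex(g, builtinWeightFns[[nm]])
      if (!is.null(d@ratWeight)) {
        expect_identical(vg == vp, TRUE)
      } else {
        expect_lt(abs(vg - vp), 1e-12 * max(1, abs(vp)))
      }
      expect_lt(abs(vg - vo), 1e-12 * max(1, abs(vo)))
    }
  }
})

test_that("rational closed forms are exact", {
  pe <- builtinPartition("polyester")
  pc <- builtinPartition("polycarbonate")
  expect_identical(coef(indexClosedForm(pe, builtinIndex("M1"))), c(a = 122, b = -8))
  expect_identical(coef(indexClosedForm(pe, builtinIndex("M2"))), c(a = 150, b = -14))
  expect_identical(coef(indexClosedForm(pe, builtinIndex("ReZG1"))), c(a = 22, b = 0))
  expect_identical(coef(indexClosedForm(pe, builtinIndex("ReZG3"))), c(a = 868, b = -88))
  expect_identical(coef(indexClosedForm(pe, builtinIndex("ReZG2"))),
                   c(a = 803 / 30, b = -127 / 60))
  expect_identical(coef(indexClosedForm(pc, builtinIndex("M1"))), c(a = 164, b = -8))
  expect_identical(coef(indexClosedForm(pc, builtinIndex("M2"))), c(a = 205, b = -12))
  expect_identical(coef(indexClosedForm(pc, builtinIndex("ReZG1"))), c(a = 29, b = 0))
  expect_identical(coef(indexClosedForm(pc, builtinIndex("ReZG2"))),
                   c(a = 5121 / 140, b = -29 / 15))
  # recomputation disagrees with the published polycarbonate ReZG3 slope 1168
  expect_identical(coef(indexClosedForm(pc, builtinIndex("ReZG3"))),
                   c(a = 1200, b = -68))
})

test_that("irrational closed forms match per-class direct summation", {
  frozen <- list(
    polyester = list(ABC = c(17.137214, -0.617138), GA = c(21.241362, -1.066025)),
    polycarbonate = list(ABC = c(22.865442, -0.707107), GA = c(28.947981, -0.996579)))
  for (pm in names(frozen)) {
    sp <- builtinPartition(pm)
    cl <- partitionClasses(sp)
    for (nm in names(frozen[[pm]])) {
      w <- mapply(builtinWeightFns[[nm]], cl$lo, cl$hi)
      direct <- c(a = sum(cl$a * w), b = sum(cl$b * w))
      got <- coef(indexClosedForm(sp, builtinIndex(nm)))
      expect_equal(got, direct, tolerance = 1e-12)
      expect_equal(unname(got), frozen[[pm]][[nm]], tolerance = 1e-6)
    }
  }
})

test_that("closed forms agree with direct evaluation over n = 1..10", {
  for (pm in c("polyester", "polycarbonate")) {
    sp <- builtinPartition(pm)
    for (nm in builtinIndexNames()) {
      d <- builtinIndex(nm)
      lf <- indexClosedForm(sp, d)
      direct <- vapply(1:10, function(n)
        indexValue(evaluatePartition(sp, n), d), 0)
      if (lf@exact) {
        expect_identical(evaluateAt(lf, 1:10), direct)
      } else {
        expect_equal(evaluateAt(lf, 1:10), direct, tolerance = 1e-12)
      }
    }
  }
})

test_that("all built-in indices strictly increase with chain length", {
  for (pm in c("polyester", "polycarbonate")) {
    sp <- builtinPartition(pm)
    for (nm in builtinIndexNames()) {
      v <- indexSeries(sp, builtinIndex(nm), 1:10)$value
      expect_true(all(diff(v) > 0))
    }
  }
})
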