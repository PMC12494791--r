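test_that("built-in partitions transcribe the polymer edge-class tables", {
  pe <- builtinPartition("polyester")
  pc <- builtinPartition("polycarbonate")
  expect_equal(nrow(partitionClasses(pe)), 7L)
  expect_equal(nrow(partitionClasses(pc)), 8L)
  expect_equal(coef(totalEdges(pe)), c(a = 23, b = -1))
  expect_equal(coef(totalEdges(pc)), c(a = 31, b = -1))
  cl <- partitionClasses(pe)
  r44 <- cl[cl$lo == 4 & cl$hi == 4, ]
  expect_equal(c(r44$a, r44$b), c(1, 0))
  expect_error(builtinPartition("polyamide"), "polyester")
})

test_that("evaluating a symbolic partition yields the substituted counts", {
  pe <- builtinPartition("polyester")
  p1 <- partitionClasses(evaluatePartition(pe, 1))
  expect_equal(p1$count, c(1, 5, 5, 2, 1, 7, 1))
  expect_equal(edgeCount(evaluatePartition(pe, 1)), 22)
  p2 <- partitionClasses(evaluatePartition(pe, 2))
  expect_equal(p2$count, c(1, 11, 9, 4, 3, 15, 2))
  expect_equal(sum(p2$count), 45)
  expect_equal(edgeCount(evaluatePartition(builtinPartition("polycarbonate"), 1)), 30)
  expect_error(evaluatePartition(pe, 0), ">= 1")
})

test_that("evaluated totals follow the edge-count closed form over n = 1..20", {
  for (pm in c("polyester", "polycarbonate")) {
    sp <- builtinPartition(pm)
    tot <- totalEdges(sp)
    for (n in 1:20)
      expect_identical(edgeCount(evaluatePartition(sp, n)), evaluateAt(tot, n))
  }
})

test_that("classes with zero frequency at a given n are dropped", {
  sp <- SymbolicPartition(lo = c(1, 2), hi = c(2, 2), a = c(1, 1), b = c(0, -1))
  expect_equal(nrow(partitionClasses(evaluatePartition(sp, 1))), 1L)
  expect_equal(nrow(partitionClasses(evaluatePartition(sp, 2))), 2L)
})

test_that("handshake consistency gives integer per-degree vertex counts", {
  dc <- degreeConsistency(builtinPartition("polyester"))
  expect_equal(dc$degree, 1:4)
  expect_equal(dc$a, c(10, 2, 8, 2))
  expect_equal(dc$b, c(1, 0, -1, 0))
  expect_equal(sum(dc$a), 22)   # 22n vertices in total
  expect_equal(sum(dc$b), 0)

  dcc <- degreeConsistency(builtinPartition("polycarbonate"))
  expect_equal(sum(dcc$a), 29)
  expect_equal(sum(dcc$b), 0)
})

test_that("unrealizable partitions fail the handshake check by name", {
  bad <- SymbolicPartition(lo = 1, hi = 3, a = 0, b = 1)
  expect_error(degreeConsistency(bad), "degree 3")
})

test_that("negative or fractional frequencies are rejected", {
  expect_error(SymbolicPartition(lo = 1, hi = 2, a = -1, b = 0),
               "negative")
  expect_error(SymbolicPartition(lo = 1, hi = 2, a = 0.5, b = 0),
               "non-integer")
})

test_that("symbolic partitions survive a JSON round trip", {
  pe <- builtinPartition("polyester")
  js <- partitionToJSON(pe)
  back <- partitionFromJSON(js)
  expect_equal(partitionClasses(back), partitionClasses(pe))
  expect_equal(back@nMin, pe@nMin)
})

test_that("linear forms evaluate exactly, including rational coefficients", {
  lf <- LinearForm(803, -127, aDen = 30, bDen = 60)
  expect_equal(coef(lf), c(a = 803 / 30, b = -127 / 60))
  # integer-valued results come out exactly integer
  lf2 <- LinearForm(3, 1, aDen = 2, bDen = 2)   # (3n + 1)/2
  expect_identical(evaluateAt(lf2, 3), 5)
  expect_identical(evaluateAt(LinearForm(23, -1), 1:3), c(22, 45, 68))
})
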