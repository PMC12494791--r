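# Independent oracles, deliberately written along different routes than the
# package internals.

# per-edge weights of a graph, as a plain vector
edgeWeights <- function(g, weightFn) {
  d <- degreeSequence(g)
  e <- partitionClasses(edgePartition(g))
  rep(mapply(weightFn, e$lo, e$hi), e$count)
}

# entropy via the probability form -sum p_i ln p_i over individual edges
oracleEntropy <- function(weights) {
  TI <- sum(weights)
  p <- weights / TI
  -sum(ifelse(p == 0, 0, p * log(p)))
}

# brute-force edge-by-edge index of an explicit graph
oracleGraphIndex <- function(g, weightFn) {
  d <- degreeSequence(g)
  e <- g@edges
  s <- 0
  for (i in seq_len(nrow(e))) s <- s + weightFn(d[e[i, 1]], d[e[i, 2]])
  s
}

# OLS of y on ln(x) by explicit normal equations
bruteForceLogFit <- function(x, y) {
  X <- cbind(1, log(x))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(b = beta[1], a = beta[2])
}

builtinWeightFns <- list(
  M1 = function(a, b) a + b,
  M2 = function(a, b) a * b,
  ReZG1 = function(a, b) (a + b) / (a * b),
  ReZG2 = function(a, b) (a * b) / (a + b),
  ReZG3 = function(a, b) (a * b) * (a + b),
  ABC = function(a, b) sqrt((a + b - 2) / (a * b)),
  GA = function(a, b) 2 * sqrt(a * b) / (a + b))

pathGraph <- function(n) MolecularGraph(cbind(1:(n - 1), 2:n))
cycleGraph <- function(n) MolecularGraph(rbind(cbind(1:(n - 1), 2:n), c(1, n)))
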