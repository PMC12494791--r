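# Seeded generators are pure functions of their seed: the caller's RNG
# state is saved and restored around every draw.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

.randomBoundedTree <- function(n, maxDegree) {
  if (n == 2L) return(matrix(c(1L, 2L), ncol = 2L))
  deg <- integer(n)
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  for (v in 2:n) {
    open <- which(deg[seq_len(v - 1L)] < maxDegree)
    if (!length(open))
      stop("infeasible spec: cannot grow a connected graph on ", n,
           " vertices with max degree ", maxDegree)
    parent <- if (length(open) == 1L) open else sample(open, 1L)
    edges[v - 1L, ] <- c(parent, v)
    deg[parent] <- deg[parent] + 1L
    deg[v] <- 1L
  }
  edges
}

.addExtraEdges <- function(edges, n, maxDegree, k) {
  deg <- tabulate(edges, nbins = n)
  adj <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  added <- 0L
  guard <- 0L
  while (added < k && guard < 200L) {
    guard <- guard + 1L
    open <- which(deg < maxDegree)
    if (length(open) < 2L) break
    pair <- sort(sample(open, 2L))
    key <- paste(pair[1], pair[2])
    if (key %in% adj) next
    edges <- rbind(edges, pair)
    adj <- c(adj, key)
    deg[pair] <- deg[pair] + 1L
    added <- added + 1L
  }
  list(edges = edges, added = added)
}

#' Random bounded-degree molecular graph
#'
#' Generates a simple connected graph with degrees capped at
#' \code{maxDegree} (default 4, the carbon valence bound of the polymer
#' chains these emulate). Trees and unicyclic graphs mirror the
#' one-ring-per-unit character of molecular graphs; \code{"connected"} adds
#' a few extra cycles for stress testing.
#'
#' @param nVertices number of vertices (\code{>= 2}; a single value or a
#'   range \code{c(lo, hi)} to sample from).
#' @param topology \code{"tree"}, \code{"unicyclic"} or \code{"connected"}.
#' @param maxDegree maximum vertex degree.
#' @param seed integer seed; the same seed always yields the same graph.
#' @return a [MolecularGraph-class].
#' @examples
#' g <- randomMolecularGraph(30, "unicyclic", seed = 7)
#' numEdges(g)   # 30
#' @export
randomMolecularGraph <- function(nVertices,
                                 topology = c("tree", "unicyclic", "connected"),
                                 maxDegree = 4L, seed = NULL) {
  topology <- match.arg(topology)
  if (any(nVertices < 2L)) stop("need at least 2 vertices")
  if (maxDegree < 1L) stop("maxDegree must be >= 1")
  .withSeed(seed, {
    n <- if (length(nVertices) > 1L)
      sample(seq(min(nVertices), max(nVertices)), 1L) else as.integer(nVertices)
    if (maxDegree == 1L && n > 2L)
      stop("infeasible spec: max degree 1 admits no connected graph on ",
           n, " > 2 vertices")
    if (topology != "tree" && n < 3L)
      stop("cyclic topologies need at least 3 vertices")
    for (attempt in 1:50) {
      edges <- .randomBoundedTree(n, maxDegree)
      if (topology == "tree") break
      k <- if (topology == "unicyclic") 1L else max(1L, n %/% 8L)
      res <- .addExtraEdges(edges, n, maxDegree, k)
      if (topology == "unicyclic" && res$added != 1L) next  # retry new tree
      edges <- res$edges
      break
    }
    if (topology == "unicyclic" && nrow(edges) != n)
      stop("infeasible spec: no unicyclic graph on ", n,
           " vertices with max degree ", maxDegree)
    MolecularGraph(edges, nVertices = n)
  })
}

#' Random realizable symbolic partition
#'
#' Draws a random bounded-degree repeat unit, turns it into a chain
#' template (head = a random terminal vertex, tail = a non-adjacent vertex
#' with spare valence) and extracts the chain's edge partition
#' symbolically from two chain lengths, verifying linearity at two more.
#' Construction by generation guarantees the result is realizable, passes
#' [degreeConsistency()], and has frequencies linear in \eqn{n} with
#' positive total slope.
#'
#' @param seed integer seed.
#' @param unitVertices vertex count of the random repeat unit (default 12).
#' @param maxDegree degree cap of the chain graphs (default 4).
#' @param topology unit topology, as in [randomMolecularGraph()].
#' @return a list with elements \code{partition}
#'   ([SymbolicPartition-class]) and \code{template}
#'   ([PolymerTemplate-class], the realizing unit).
#' @examples
#' rp <- randomSymbolicPartition(seed = 1)
#' degreeConsistency(rp$partition)
#' @export
randomSymbolicPartition <- function(seed, unitVertices = 12L, maxDegree = 4L,
                                    topology = "unicyclic") {
  if (unitVertices < 4L) stop("unit needs at least 4 vertices")
  for (attempt in 0:49) {
    g <- randomMolecularGraph(unitVertices, topology, maxDegree,
                              seed = seed + 1000003L * attempt)
    deg <- degreeSequence(g)
    leaves <- which(deg == 1L)
    if (!length(leaves)) next
    adj <- cbind(g@edges, g@edges[, 2:1])
    tmpl <- NULL
    for (head in leaves) {
      nbr <- function(v) adj[adj[, 1] == v, 2]
      forbidden <- c(head, nbr(head))
      cand <- setdiff(which(deg < maxDegree), forbidden)
      cand <- cand[!vapply(cand, function(v) head %in% nbr(v), TRUE)]
      if (length(cand)) {
        tail <- cand[[1L]]
        tmpl <- PolymerTemplate("random", g@edges, unitVertices, head, tail)
        break
      }
    }
    if (is.null(tmpl)) next
    counts <- lapply(1:4, function(n)
      partitionClasses(edgePartition(assembleChain(tmpl, n))))
    key <- function(df) paste(df$lo, df$hi)
    keys <- sort(unique(unlist(lapply(counts, key))))
    cnt <- vapply(counts, function(df) {
      v <- numeric(length(keys)); names(v) <- keys
      v[key(df)] <- df$count
      v
    }, numeric(length(keys)))
    a <- cnt[, 2] - cnt[, 1]
    b <- cnt[, 1] - a
    if (any(abs(a %o% c(3, 4) + b %o% c(1, 1) - cnt[, 3:4]) > 0))
      next  # degree environment of the attachments drifted; redraw
    parts <- strsplit(keys, " ", fixed = TRUE)
    sp <- SymbolicPartition(
      lo = as.integer(vapply(parts, `[`, "", 1L)),
      hi = as.integer(vapply(parts, `[`, "", 2L)),
      a = a, b = b)
    return(list(partition = sp, template = tmpl))
  }
  stop("could not realize a random partition for this configuration")
}

#' Noisy logarithmic series for regression testing
#'
#' Draws positive \code{x} and responses
#' \eqn{y = a \ln x + b + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}.
#'
#' @param a,b true slope and intercept.
#' @param sigma noise standard deviation (\code{>= 0}).
#' @param n number of observations (\code{>= 3}).
#' @param seed integer seed.
#' @return data.frame with columns \code{x}, \code{y}.
#' @examples
#' d <- noisyLogSeries(0.8, 0.3, 0.01, 200, seed = 1)
#' coef(fitLogModel(d$x, d$y))
#' @export
noisyLogSeries <- function(a, b, sigma, n, seed = NULL) {
  if (!.isWholeNumber(n) || n < 3) stop("n must be an integer >= 3")
  if (sigma < 0) stop("sigma must be >= 0")
  .withSeed(seed, {
    x <- exp(stats::runif(n, 0, 5))
    y <- a * log(x) + b + stats::rnorm(n, 0, sigma)
    data.frame(x = x, y = y)
  })
}
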