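#' Construct a molecular graph from an edge list
#'
#' @param edges two-column matrix (or data.frame) of 1-based vertex id
#'   pairs, one row per undirected edge.
#' @param nVertices number of vertices; defaults to the largest id seen.
#' @param labels optional character vector of vertex labels.
#' @return a [MolecularGraph-class].
#' @examples
#' MolecularGraph(rbind(c(1, 2), c(2, 3)))   # path on 3 vertices
#' @export
MolecularGraph <- function(edges, nVertices = NULL, labels = character()) {
  e <- as.matrix(edges)
  if (length(e) == 0L) e <- matrix(integer(), ncol = 2L)
  storage.mode(e) <- "integer"
  if (is.null(nVertices)) nVertices <- max(e, 1L)
  if (nrow(e)) {
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  dimnames(e) <- NULL
  new("MolecularGraph", edges = e, nVertices = as.integer(nVertices),
      labels = as.character(labels))
}

#' @rdname MolecularGraph
#' @param g a [MolecularGraph-class].
#' @export
numVertices <- function(g) { stopifnot(is(g, "MolecularGraph")); g@nVertices }

#' @rdname MolecularGraph
#' @export
numEdges <- function(g) { stopifnot(is(g, "MolecularGraph")); nrow(g@edges) }

#' Vertex degrees
#'
#' @param g a [MolecularGraph-class].
#' @return integer vector of vertex degrees, indexed by vertex id.
#' @export
degreeSequence <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  tabulate(g@edges, nbins = g@nVertices)
}

#' Convert to an igraph object
#'
#' @param g a [MolecularGraph-class].
#' @return an \pkg{igraph} undirected graph.
#' @export
asIgraph <- function(g) {
  stopifnot(is(g, "MolecularGraph"))
  ig <- igraph::make_empty_graph(n = g@nVertices, directed = FALSE)
  igraph::add_edges(ig, t(g@edges))
}

#' Is the graph connected?
#'
#' @param g a [MolecularGraph-class].
#' @return logical.
#' @export
isConnected <- function(g) {
  igraph::is_connected(asIgraph(g))
}

#' @describeIn edgePartition group the edges of an explicit graph by
#'   endpoint-degree pairs.
setMethod("edgePartition", "MolecularGraph", function(g) {
  if (nrow(g@edges) == 0L) stop("graph has no edges")
  d <- degreeSequence(g)
  du <- d[g@edges[, 1]]; dv <- d[g@edges[, 2]]
  lo <- pmin(du, dv); hi <- pmax(du, dv)
  key <- paste(lo, hi)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  EdgePartition(lo = as.integer(vapply(parts, `[`, "", 1L)),
                hi = as.integer(vapply(parts, `[`, "", 2L)),
                count = as.integer(tab))
})

#' Read / write plain-text edge lists
#'
#' One edge per line: two whitespace-separated 1-based vertex ids.
#' Lines starting with \code{#} are comments. \code{writeEdgeList} records
#' the vertex count in a leading comment so isolated vertices survive a
#' round trip.
#'
#' @param path file path.
#' @param nVertices optional vertex count override when reading.
#' @return \code{readEdgeList}: a [MolecularGraph-class].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeEdgeList(assembleChain(polymerTemplate("polyester"), 1), f)
#' g <- readEdgeList(f)
#' @export
readEdgeList <- function(path, nVertices = NULL) {
  ln <- readLines(path)
  nv <- NULL
  hd <- grep("^#\\s*vertices:", ln, value = TRUE)
  if (length(hd)) nv <- as.integer(sub("^#\\s*vertices:\\s*", "", hd[1]))
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  if (!length(ln)) stop("no edges in ", path)
  toks <- strsplit(ln, "\\s+")
  if (any(lengths(toks) != 2L)) stop("each edge line needs two vertex ids")
  e <- matrix(as.integer(unlist(toks)), ncol = 2L, byrow = TRUE)
  if (anyNA(e) || any(e < 1L)) stop("vertex ids must be positive integers")
  MolecularGraph(e, nVertices = if (is.null(nVertices)) nv else nVertices)
}

#' @rdname readEdgeList
#' @param g a [MolecularGraph-class] to write.
#' @export
writeEdgeList <- function(g, path) {
  stopifnot(is(g, "MolecularGraph"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# vertices: %d", g@nVertices), con)
  writeLines(sprintf("%d %d", g@edges[, 1], g@edges[, 2]), con)
  invisible(path)
}

#' Read / write GraphML
#'
#' Thin wrappers over \pkg{igraph}'s GraphML support.
#'
#' @param path file path.
#' @return \code{readGraphML}: a [MolecularGraph-class].
#' @export
readGraphML <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  e <- igraph::as_edgelist(ig, names = FALSE)
  labs <- igraph::vertex_attr(ig, "label")
  MolecularGraph(e, nVertices = igraph::vcount(ig),
                 labels = if (is.null(labs)) character() else labs)
}

#' @rdname readGraphML
#' @param g a [MolecularGraph-class] to write.
#' @export
writeGraphML <- function(g, path) {
  stopifnot(is(g, "MolecularGraph"))
  ig <- asIgraph(g)
  if (length(g@labels))
    ig <- igraph::set_vertex_attr(ig, "label", value = g@labels)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d vertices, %d edges\n",
              object@nVertices, nrow(object@edges)))
  invisible(object)
})
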