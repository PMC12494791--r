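# Unit realizations of the built-in partitions. The published structures are
# drawings only; these edge lists are explicit graphs constructed so that the
# assembled n-unit chain reproduces the built-in symbolic partition for every
# n >= 1 (the chain-oracle tests check n = 1..5). Any realization with that
# property is equivalent for degree-based analysis.
#
# Polyester unit, 22 vertices / 22 edges (unicyclic, one ring per unit):
#   1..7  ring carbons (degree 3; 7 forms the ring substituent),
#   8,9   degree-4 pair, 10,11 degree-2 bridges, 12..22 degree-1 terminals.
# head = 17 (a terminal on the degree-4 vertex 8), tail = 10 (degree-2,
# neighbours of degree 1 and 3): joining tail -> head reclassifies exactly
# the edge classes needed to keep Table-style frequencies linear in n.
.polyesterUnit <- list(
  edges = rbind(
    c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1),   # ring
    c(1, 7), c(7, 12), c(7, 10), c(10, 22),                  # substituent arm
    c(2, 13), c(3, 14), c(4, 15), c(5, 16),                  # ring terminals
    c(6, 11), c(11, 8), c(8, 9),                             # bridge + quaternary pair
    c(8, 17), c(8, 18), c(9, 19), c(9, 20), c(9, 21)),       # terminals
  nVertices = 22L, head = 17L, tail = 10L)

# Polycarbonate unit, 29 vertices / 30 edges (two rings per unit):
#   1..8  degree-3 vertices (1..4 a 4-ring, 5,6 + 12,13 the second ring),
#   9..11 degree-4 backbone, 12..17 degree-2 vertices, 18..29 terminals.
# head = 29 (the terminal of the single (1,2) edge), tail = 16 (middle of
# the degree-2 chain 15-16-17).
.polycarbonateUnit <- list(
  edges = rbind(
    c(1, 2), c(2, 3), c(3, 4), c(1, 4),                      # ring A
    c(5, 6), c(6, 12), c(12, 13), c(5, 13),                  # ring B
    c(4, 14), c(5, 14),                                      # bridge into ring B
    c(7, 8),                                                 # degree-3 pair
    c(9, 10), c(10, 11), c(1, 10), c(7, 10),                 # degree-4 backbone
    c(9, 18), c(9, 19), c(9, 20), c(11, 21), c(11, 22), c(11, 23),
    c(7, 15), c(15, 16), c(16, 17), c(17, 29),               # degree-2 chain
    c(2, 24), c(3, 25), c(6, 26), c(8, 27), c(8, 28)),       # terminals
  nVertices = 29L, head = 29L, tail = 16L)

.templates <- list(polyester = .polyesterUnit,
                   polycarbonate = .polycarbonateUnit)

#' Built-in polymer repeat-unit templates
#'
#' Explicit repeat units whose assembled chains ([assembleChain()]) have
#' \eqn{22n} vertices / \eqn{23n - 1} edges (polyester) resp. \eqn{29n}
#' vertices / \eqn{31n - 1} edges (polycarbonate) and reproduce the
#' corresponding [builtinPartition()] at every chain length.
#'
#' @param polymer \code{"polyester"} or \code{"polycarbonate"}.
#' @return a [PolymerTemplate-class].
#' @examples
#' polymerTemplate("polycarbonate")
#' @export
polymerTemplate <- function(polymer) {
  if (!is.character(polymer) || length(polymer) != 1L ||
      !polymer %in% names(.templates))
    stop("unknown polymer '", paste(polymer, collapse = ","),
         "'; valid identifiers: ", paste(names(.templates), collapse = ", "))
  t <- .templates[[polymer]]
  PolymerTemplate(polymer, t$edges, t$nVertices, t$head, t$tail)
}

#' Construct a repeat-unit template
#'
#' @param name template identifier.
#' @param unitEdges two-column matrix of local 1-based edges.
#' @param unitVertices vertex count of one unit.
#' @param head,tail local attachment vertex ids; chains are joined by an
#'   edge from the tail of unit \eqn{k} to the head of unit \eqn{k + 1}.
#' @return a [PolymerTemplate-class].
#' @export
PolymerTemplate <- function(name, unitEdges, unitVertices, head, tail) {
  e <- as.matrix(unitEdges); storage.mode(e) <- "integer"
  new("PolymerTemplate", name = name, unitEdges = e,
      unitVertices = as.integer(unitVertices),
      head = as.integer(head), tail = as.integer(tail))
}

#' Assemble an n-unit polymer chain graph
#'
#' Lays down \code{n} copies of the repeat unit and joins consecutive units
#' by a single connector edge (tail of unit \eqn{k} to head of unit
#' \eqn{k + 1}), giving \code{n * unitVertices} vertices and
#' \code{n * unitEdges + n - 1} edges.
#'
#' @param template a [PolymerTemplate-class].
#' @param n number of repeat units, \code{>= 1}.
#' @return a connected simple [MolecularGraph-class].
#' @examples
#' g <- assembleChain(polymerTemplate("polyester"), 3)
#' numVertices(g); numEdges(g)   # 66, 68
#' @export
assembleChain <- function(template, n) {
  stopifnot(is(template, "PolymerTemplate"))
  if (!.isWholeNumber(n) || n < 1) stop("n must be a positive integer")
  n <- as.integer(n)
  m <- template@unitVertices
  offs <- rep((0:(n - 1)) * m, each = nrow(template@unitEdges))
  edges <- template@unitEdges[rep(seq_len(nrow(template@unitEdges)), n), ,
                              drop = FALSE] + offs
  if (n > 1L) {
    k <- 0:(n - 2)
    conn <- cbind(template@tail + k * m, template@head + (k + 1L) * m)
    edges <- rbind(edges, conn)
  }
  MolecularGraph(edges, nVertices = n * m)
}

setMethod("show", "PolymerTemplate", function(object) {
  cat(sprintf(
    "PolymerTemplate '%s': %d vertices, %d edges per unit (head %d, tail %d)\n",
    object@name, object@unitVertices, nrow(object@unitEdges),
    object@head, object@tail))
  invisible(object)
})
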