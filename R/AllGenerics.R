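#' Evaluate a closed form at a chain length
#'
#' @param x a [LinearForm-class] or [EntropyClosedForm-class].
#' @param n chain length(s), integer-valued.
#' @return numeric value(s) of the form at \code{n}.
#' @examples
#' evaluateAt(LinearForm(23, -1), 1:3)
#' @export
setGeneric("evaluateAt", function(x, n) standardGeneric("evaluateAt"))

#' Extract the degree-based edge partition of a graph
#'
#' Each edge contributes one count to the class given by the unordered pair
#' of its endpoint degrees.
#'
#' @param g a [MolecularGraph-class] with at least one edge.
#' @return an [EdgePartition-class]; its counts sum to the edge number.
#' @examples
#' edgePartition(assembleChain(polymerTemplate("polyester"), 1))
#' @export
setGeneric("edgePartition", function(g) standardGeneric("edgePartition"))

#' Degree-based topological index value
#'
#' Sum of the index weight \eqn{f(d_u, d_v)} over edges, computed either
#' from a grouped [EdgePartition-class] (exact rational arithmetic for the
#' rational built-ins) or edge-by-edge from an explicit
#' [MolecularGraph-class]; the two routes agree by construction and are
#' cross-checked in the test-suite.
#'
#' @param x an [EdgePartition-class] or [MolecularGraph-class].
#' @param index an [IndexDefinition-class], see [builtinIndex()].
#' @return numeric index value.
#' @examples
#' indexValue(evaluatePartition(builtinPartition("polyester"), 1),
#'            builtinIndex("M1"))
#' @export
setGeneric("indexValue", function(x, index) standardGeneric("indexValue"))

#' Shannon edge-entropy under a degree-based index
#'
#' Computes \eqn{ENT = \ln TI - (1/TI) \sum_i U_i f_i \ln f_i} with
#' \eqn{TI = \sum_i U_i f_i}, the Shannon entropy of the edge distribution
#' weighted proportionally to each edge's index contribution. Natural
#' logarithms throughout; the convention \eqn{0 \ln 0 = 0} lets zero-weight
#' classes (e.g. ABC on a (1,1) edge) contribute nothing.
#'
#' @param x an [EdgePartition-class] or [MolecularGraph-class].
#' @param index an [IndexDefinition-class].
#' @return entropy in nats, between 0 and \eqn{\ln m} for \eqn{m} edges.
#' @examples
#' entropyValue(evaluatePartition(builtinPartition("polyester"), 1),
#'              builtinIndex("M1"))
#' @export
setGeneric("entropyValue", function(x, index) standardGeneric("entropyValue"))
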