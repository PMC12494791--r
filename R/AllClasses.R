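#' Linear form a*n + b with optional exact rational coefficients
#'
#' A closed-form expression \eqn{a \cdot n + b} in the chain length \eqn{n}.
#' Edge-class frequencies, vertex counts per degree and the rational
#' topological indices of polymer chains are all of this shape. Coefficients
#' are stored as integer numerator/denominator pairs; when \code{exact} is
#' \code{TRUE} evaluation is exact rational arithmetic, otherwise the
#' numerators hold plain double values (denominators 1), as needed for the
#' irrational ABC and GA indices.
#'
#' @slot aNum,aDen numerator and denominator of the slope \eqn{a}.
#' @slot bNum,bDen numerator and denominator of the constant \eqn{b}.
#' @slot exact logical; \code{TRUE} when the coefficients are exact rationals.
#'
#' @seealso [LinearForm()], [evaluateAt()], [indexClosedForm()]
#' @export
setClass("LinearForm",
  representation(aNum = "numeric", aDen = "numeric",
                 bNum = "numeric", bDen = "numeric", exact = "logical"),
  prototype(aNum = 0, aDen = 1, bNum = 0, bDen = 1, exact = TRUE))

setValidity("LinearForm", function(object) {
  msg <- character()
  if (length(object@aNum) != 1L || length(object@bNum) != 1L ||
      length(object@aDen) != 1L || length(object@bDen) != 1L)
    msg <- c(msg, "coefficients must be scalars")
  if (any(c(object@aDen, object@bDen) == 0))
    msg <- c(msg, "denominators must be non-zero")
  if (object@exact &&
      !all(.isWholeNumber(c(object@aNum, object@aDen, object@bNum, object@bDen))))
    msg <- c(msg, "exact forms require integer numerators and denominators")
  if (length(msg)) msg else TRUE
})

#' Symbolic degree-based edge partition
#'
#' Maps unordered degree pairs (edge classes) of a polymer chain graph to
#' frequencies that are linear functions \eqn{a \cdot n + b} of the number of
#' repeat units \eqn{n}. The built-in polyester and polycarbonate partitions
#' are of this form, with integer coefficients and 7 resp. 8 classes.
#'
#' @slot classes data.frame with columns \code{lo}, \code{hi} (canonical
#'   degree pair, \code{lo <= hi}), \code{a}, \code{b} (frequency
#'   coefficients). Rows are sorted lexicographically by (lo, hi).
#' @slot nMin smallest chain length at which the partition is valid.
#'
#' @seealso [builtinPartition()], [evaluatePartition()], [degreeConsistency()]
#' @export
setClass("SymbolicPartition",
  representation(classes = "data.frame", nMin = "integer"))

setValidity("SymbolicPartition", function(object) {
  cl <- object@classes
  need <- c("lo", "hi", "a", "b")
  if (!all(need %in% names(cl)))
    return(sprintf("classes must have columns %s", paste(need, collapse = ", ")))
  if (nrow(cl) == 0L) return("partition has no classes")
  if (any(cl$lo > cl$hi)) return("degree pairs must be canonical (lo <= hi)")
  if (any(cl$lo < 1L)) return("degrees must be >= 1")
  if (anyDuplicated(cl[, c("lo", "hi")])) return("duplicated edge class")
  probe <- object@nMin + 0:20
  for (i in seq_len(nrow(cl))) {
    v <- cl$a[i] * probe + cl$b[i]
    if (any(v < 0))
      return(sprintf("class (%d,%d) has negative frequency in probe range",
                     cl$lo[i], cl$hi[i]))
    if (!all(.isWholeNumber(v)))
      return(sprintf("class (%d,%d) has non-integer frequency in probe range",
                     cl$lo[i], cl$hi[i]))
  }
  TRUE
})

#' Concrete edge partition of a molecular graph
#'
#' Counts of edges grouped by the unordered pair of endpoint degrees, either
#' extracted from an explicit graph ([edgePartition()]) or obtained by
#' evaluating a [SymbolicPartition-class] at a chain length
#' ([evaluatePartition()]).
#'
#' @slot classes data.frame with columns \code{lo}, \code{hi}, \code{count}
#'   (positive integers), sorted by (lo, hi).
#'
#' @seealso [indexValue()], [entropyValue()]
#' @export
setClass("EdgePartition", representation(classes = "data.frame"))

setValidity("EdgePartition", function(object) {
  cl <- object@classes
  if (!all(c("lo", "hi", "count") %in% names(cl)))
    return("classes must have columns lo, hi, count")
  if (nrow(cl) == 0L) return("empty partition")
  if (any(cl$lo > cl$hi)) return("degree pairs must be canonical (lo <= hi)")
  if (any(cl$count <= 0) || !all(.isWholeNumber(cl$count)))
    return("counts must be positive integers")
  if (anyDuplicated(cl[, c("lo", "hi")])) return("duplicated edge class")
  TRUE
})

#' Simple undirected molecular graph
#'
#' Atoms are vertices (contiguous integer ids starting at 1), bonds are
#' edges. Loops and parallel edges are rejected; this is the plain graph
#' model under which degree-based indices are defined.
#'
#' @slot edges two-column integer matrix of vertex id pairs, one row per
#'   edge, stored with the smaller id first and rows sorted.
#' @slot nVertices number of vertices.
#' @slot labels optional character vector of vertex labels (e.g. element
#'   symbols), length 0 or \code{nVertices}.
#'
#' @seealso [MolecularGraph()], [readEdgeList()], [assembleChain()]
#' @export
setClass("MolecularGraph",
  representation(edges = "matrix", nVertices = "integer", labels = "character"))

setValidity("MolecularGraph", function(object) {
  e <- object@edges
  n <- object@nVertices
  if (ncol(e) != 2L) return("edges must be a two-column matrix")
  if (n < 1L) return("graph must have at least one vertex")
  if (nrow(e)) {
    if (any(e < 1L) || any(e > n)) return("edge endpoint out of range")
    if (any(e[, 1] == e[, 2])) return("loops are not allowed")
    if (any(e[, 1] > e[, 2])) return("edges must be stored with lo id first")
    if (anyDuplicated(e)) return("parallel edges are not allowed")
  }
  if (length(object@labels) && length(object@labels) != n)
    return("labels must be empty or one per vertex")
  TRUE
})

#' Polymer repeat-unit template
#'
#' An explicit repeat unit plus head/tail attachment vertices. Assembling
#' \eqn{k} copies joined tail-to-head by \eqn{k - 1} connector edges yields
#' the n-unit chain graph ([assembleChain()]); the built-in templates
#' reproduce the corresponding symbolic partitions at every chain length.
#'
#' @slot name template identifier.
#' @slot unitEdges two-column integer matrix of local (within-unit) edges.
#' @slot unitVertices vertex count of one unit.
#' @slot head local id of the vertex that receives the connector from the
#'   previous unit.
#' @slot tail local id of the vertex that sends the connector to the next
#'   unit.
#'
#' @seealso [polymerTemplate()], [assembleChain()]
#' @export
setClass("PolymerTemplate",
  representation(name = "character", unitEdges = "matrix",
                 unitVertices = "integer", head = "integer", tail = "integer"))

setValidity("PolymerTemplate", function(object) {
  if (any(c(object@head, object@tail) < 1L) ||
      any(c(object@head, object@tail) > object@unitVertices))
    return("attachment ids out of range")
  if (object@head == object@tail) return("head and tail must differ")
  TRUE
})

#' Degree-based index definition
#'
#' A named symmetric weight function \eqn{f(d_u, d_v)} on endpoint degrees.
#' The index of a graph is the sum of \eqn{f} over its edges. Built-in
#' definitions cover M1, M2, ReZG1, ReZG2, ReZG3, ABC and GA; users may
#' register any further symmetric weight via [IndexDefinition()].
#'
#' @slot name index name.
#' @slot weight function of two degrees returning a finite non-negative
#'   numeric weight.
#' @slot ratWeight either \code{NULL} or a function returning the weight as
#'   an exact rational \code{c(num, den)}; present for the five rational
#'   built-ins and used for exact closed forms.
#'
#' @seealso [builtinIndex()], [indexValue()], [indexClosedForm()]
#' @export
setClass("IndexDefinition",
  representation(name = "character", weight = "function", ratWeight = "ANY"))

setValidity("IndexDefinition", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("index needs a non-empty name")
  for (a in 1:8) for (b in a:8) {
    wa <- object@weight(a, b); wb <- object@weight(b, a)
    if (!is.finite(wa) || !is.finite(wb))
      return(sprintf("weight not finite at degrees (%d,%d)", a, b))
    if (wa < 0) return(sprintf("weight negative at degrees (%d,%d)", a, b))
    if (abs(wa - wb) > 1e-12)
      return(sprintf("weight not symmetric at degrees (%d,%d)", a, b))
    if (!is.null(object@ratWeight)) {
      r <- object@ratWeight(a, b)
      if (abs(r[1] / r[2] - wa) > 1e-12)
        return(sprintf("rational weight disagrees at degrees (%d,%d)", a, b))
    }
  }
  TRUE
})

#' Entropy closed form ln I(n) - S(n)/I(n)
#'
#' The edge-entropy of an n-unit chain under a degree-based index is
#' \eqn{ENT(n) = \ln I(n) - S(n)/I(n)} where \eqn{I(n)} is the index closed
#' form and \eqn{S(n) = \sum_i U_i(n) f_i \ln f_i} the weighted log-sum;
#' both are linear in \eqn{n}.
#'
#' @slot index [LinearForm-class] for \eqn{I(n)}.
#' @slot logSum [LinearForm-class] for \eqn{S(n)}.
#' @slot indexName name of the underlying index.
#'
#' @seealso [entropyClosedForm()], [evaluateAt()]
#' @export
setClass("EntropyClosedForm",
  representation(index = "LinearForm", logSum = "LinearForm",
                 indexName = "character"))

#' Logarithmic regression fit Y = a ln X + b
#'
#' Ordinary least-squares fit of a response on the natural logarithm of a
#' positive regressor, with the usual goodness-of-fit statistics.
#'
#' @slot a slope (coefficient of \eqn{\ln X}).
#' @slot b intercept.
#' @slot aSE standard error of the slope estimate.
#' @slot R correlation coefficient, \eqn{sign(a)\sqrt{R^2}}.
#' @slot R2 coefficient of determination.
#' @slot SE standard error of the estimate, \eqn{\sqrt{RSS/(N-2)}}.
#' @slot F F-statistic of the regression (\code{Inf} for an exact fit).
#' @slot p upper-tail p-value of the F-statistic.
#' @slot N number of observations.
#'
#' @seealso [fitLogModel()], [predict,LogFit-method]
#' @export
setClass("LogFit",
  representation(a = "numeric", b = "numeric", aSE = "numeric", R = "numeric",
                 R2 = "numeric", SE = "numeric", F = "numeric", p = "numeric",
                 N = "integer"))

setValidity("LogFit", function(object) {
  if (object@R2 < -1e-12 || object@R2 > 1 + 1e-12) return("R2 outside [0, 1]")
  if (object@SE < 0) return("SE must be non-negative")
  if (object@p < 0 || object@p > 1) return("p outside [0, 1]")
  TRUE
})
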