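# The seven degree-based weights. Rational ones carry an exact num/den
# version used for exact closed forms; ABC and GA are irrational.
.builtinIndices <- list(
  M1 = list(w = function(a, b) a + b,
            r = function(a, b) c(a + b, 1)),
  M2 = list(w = function(a, b) a * b,
            r = function(a, b) c(a * b, 1)),
  ReZG1 = list(w = function(a, b) (a + b) / (a * b),
               r = function(a, b) c(a + b, a * b)),
  ReZG2 = list(w = function(a, b) (a * b) / (a + b),
               r = function(a, b) c(a * b, a + b)),
  ReZG3 = list(w = function(a, b) (a * b) * (a + b),
               r = function(a, b) c((a * b) * (a + b), 1)),
  ABC = list(w = function(a, b) sqrt((a + b - 2) / (a * b)), r = NULL),
  GA = list(w = function(a, b) 2 * sqrt(a * b) / (a + b), r = NULL))

#' Names of the built-in index definitions
#'
#' @return character vector: M1, M2, ReZG1, ReZG2, ReZG3, ABC, GA.
#' @export
builtinIndexNames <- function() names(.builtinIndices)

#' Built-in degree-based index definitions
#'
#' Weights per edge with endpoint degrees \eqn{(d_u, d_v)}:
#' \describe{
#'   \item{M1}{\eqn{d_u + d_v} (first Zagreb)}
#'   \item{M2}{\eqn{d_u d_v} (second Zagreb)}
#'   \item{ReZG1}{\eqn{(d_u + d_v)/(d_u d_v)}}
#'   \item{ReZG2}{\eqn{(d_u d_v)/(d_u + d_v)}}
#'   \item{ReZG3}{\eqn{(d_u d_v)(d_u + d_v)}}
#'   \item{ABC}{\eqn{\sqrt{(d_u + d_v - 2)/(d_u d_v)}} (atom-bond connectivity)}
#'   \item{GA}{\eqn{2\sqrt{d_u d_v}/(d_u + d_v)} (geometric-arithmetic)}
#' }
#'
#' @param name one of [builtinIndexNames()].
#' @return an [IndexDefinition-class].
#' @examples
#' builtinIndex("ABC")
#' @export
builtinIndex <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.builtinIndices))
    stop("unknown index '", paste(name, collapse = ","),
         "'; registry: ", paste(names(.builtinIndices), collapse = ", "))
  d <- .builtinIndices[[name]]
  new("IndexDefinition", name = name, weight = d$w, ratWeight = d$r)
}

#' Define a custom degree-based index
#'
#' Registers a user weight function; symmetry and finiteness are validated
#' by probing degrees 1..8.
#'
#' @param name index name.
#' @param weight symmetric function of two degrees returning a finite
#'   non-negative weight.
#' @param ratWeight optional exact version returning \code{c(num, den)};
#'   enables exact rational closed forms.
#' @return an [IndexDefinition-class].
#' @examples
#' sumConn <- IndexDefinition("SC", function(a, b) 1 / sqrt(a + b))
#' @export
IndexDefinition <- function(name, weight, ratWeight = NULL) {
  new("IndexDefinition", name = name, weight = weight, ratWeight = ratWeight)
}

setMethod("show", "IndexDefinition", function(object) {
  cat(sprintf("IndexDefinition '%s'%s\n", object@name,
              if (is.null(object@ratWeight)) "" else " (exact rational)"))
  invisible(object)
})

# exact rational index value of a concrete partition; NULL if not rational
.ratIndexValue <- function(p, index) {
  if (is.null(index@ratWeight)) return(NULL)
  cl <- p@classes
  rw <- mapply(index@ratWeight, cl$lo, cl$hi)
  .ratWeightedSum(cl$count, rw[1, ], rw[2, ])
}

#' @describeIn indexValue grouped summation \eqn{\sum_i U_i f(lo_i, hi_i)}
#'   over partition classes; exact for the rational built-ins.
setMethod("indexValue", signature("EdgePartition", "IndexDefinition"),
  function(x, index) {
    r <- .ratIndexValue(x, index)
    if (!is.null(r)) return(unname(r[1] / r[2]))
    cl <- x@classes
    sum(cl$count * mapply(index@weight, cl$lo, cl$hi))
  })

#' @describeIn indexValue brute-force edge-by-edge summation over an
#'   explicit graph.
setMethod("indexValue", signature("MolecularGraph", "IndexDefinition"),
  function(x, index) {
    if (nrow(x@edges) == 0L) stop("graph has no edges")
    d <- degreeSequence(x)
    du <- d[x@edges[, 1]]; dv <- d[x@edges[, 2]]
    if (!is.null(index@ratWeight)) {
      rw <- mapply(index@ratWeight, du, dv)
      r <- .ratWeightedSum(rep(1, ncol(rw)), rw[1, ], rw[2, ])
      return(unname(r[1] / r[2]))
    }
    sum(mapply(index@weight, du, dv))
  })

#' Closed form of an index over a symbolic partition
#'
#' Because class frequencies are linear in the chain length \eqn{n} and
#' weights are per-class constants, the index is linear in \eqn{n}. The
#' coefficients are obtained by two-point interpolation at \eqn{n = 1, 2}
#' (exact rational arithmetic for the rational built-ins) and verified at
#' \eqn{n = 3}.
#'
#' @param sp a [SymbolicPartition-class].
#' @param index an [IndexDefinition-class].
#' @return a [LinearForm-class].
#' @examples
#' indexClosedForm(builtinPartition("polyester"), builtinIndex("M1")) # 122n - 8
#' @export
indexClosedForm <- function(sp, index) {
  stopifnot(is(sp, "SymbolicPartition"), is(index, "IndexDefinition"))
  n0 <- sp@nMin
  p <- lapply(n0 + 0:2, function(n) evaluatePartition(sp, n))
  if (!is.null(index@ratWeight)) {
    v <- lapply(p, .ratIndexValue, index = index)
    a <- .ratSub(v[[2]], v[[1]])
    b <- .ratSub(v[[1]], .ratScale(a, n0))
    lf <- .lfFromRat(a, b)
    chk <- .ratAdd(.ratScale(a, n0 + 2), b)
    if (abs(chk[1] / chk[2] - v[[3]][1] / v[[3]][2]) > 0)
      stop("internal error: closed form fails verification at n = ", n0 + 2)
  } else {
    v <- vapply(p, indexValue, 0, index = index)
    a <- v[2] - v[1]
    b <- v[1] - a * n0
    lf <- LinearForm(a, b, exact = FALSE)
    if (abs(a * (n0 + 2) + b - v[3]) > 1e-9 * max(1, abs(v[3])))
      stop("internal error: closed form fails verification at n = ", n0 + 2)
  }
  lf
}

#' Index values over a range of chain lengths
#'
#' @param sp a [SymbolicPartition-class].
#' @param index an [IndexDefinition-class].
#' @param n integer vector of chain lengths.
#' @return data.frame with columns \code{n}, \code{index}, \code{value}.
#' @export
indexSeries <- function(sp, index, n = 1:10) {
  vals <- vapply(n, function(k)
    indexValue(evaluatePartition(sp, k), index), 0)
  data.frame(n = n, index = index@name, value = vals)
}
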