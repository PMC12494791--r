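#' Construct a linear form a*n + b
#'
#' @param a,b slope and constant. When both are integer-valued (or given as
#'   rationals via \code{aDen}/\code{bDen}) the form is exact.
#' @param aDen,bDen optional denominators for rational coefficients.
#' @param exact force exact/inexact storage; by default exactness is
#'   inferred from the coefficients being whole numbers.
#' @return a [LinearForm-class].
#' @examples
#' LinearForm(23, -1)            # edge count of the polyester chain
#' LinearForm(803, -127, aDen = 30, bDen = 60)
#' @export
LinearForm <- function(a, b, aDen = 1, bDen = 1, exact = NULL) {
  if (is.null(exact))
    exact <- all(.isWholeNumber(c(a, b, aDen, bDen)))
  if (exact) {
    ar <- .ratReduce(round(a), round(aDen))
    br <- .ratReduce(round(b), round(bDen))
    new("LinearForm", aNum = ar[1], aDen = ar[2],
        bNum = br[1], bDen = br[2], exact = TRUE)
  } else {
    new("LinearForm", aNum = a / aDen, aDen = 1,
        bNum = b / bDen, bDen = 1, exact = FALSE)
  }
}

.lfFromRat <- function(aRat, bRat) {
  new("LinearForm", aNum = aRat[1], aDen = aRat[2],
      bNum = bRat[1], bDen = bRat[2], exact = TRUE)
}

#' @describeIn evaluateAt exact rational evaluation when the form is exact;
#'   in particular integer-valued results are returned without rounding
#'   error.
setMethod("evaluateAt", "LinearForm", function(x, n) {
  if (x@exact) {
    den <- x@aDen * x@bDen
    (x@aNum * x@bDen * n + x@bNum * x@aDen) / den
  } else {
    x@aNum * n + x@bNum
  }
})

#' Coefficients of a closed form
#'
#' @param object a [LinearForm-class] or [LogFit-class].
#' @param ... unused.
#' @return named numeric vector \code{c(a, b)} (slope, constant/intercept).
#' @examples
#' coef(indexClosedForm(builtinPartition("polyester"), builtinIndex("M1")))
#' @export
setMethod("coef", "LinearForm", function(object, ...) {
  c(a = unname(object@aNum / object@aDen),
    b = unname(object@bNum / object@bDen))
})

.lfFormat <- function(x) {
  co <- coef(x)
  sprintf("%.6g*n %s %.6g", co[["a"]],
          if (co[["b"]] < 0) "-" else "+", abs(co[["b"]]))
}

setMethod("show", "LinearForm", function(object) {
  cat("LinearForm:", .lfFormat(object),
      if (object@exact) "(exact)\n" else "\n")
  invisible(object)
})
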