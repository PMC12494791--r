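.canonClasses <- function(df) {
  swap <- df$lo > df$hi
  if (any(swap)) {
    tmp <- df$lo[swap]; df$lo[swap] <- df$hi[swap]; df$hi[swap] <- tmp
  }
  df <- df[order(df$lo, df$hi), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Construct a symbolic edge partition
#'
#' @param lo,hi integer degree pairs of the edge classes (canonicalized to
#'   \code{lo <= hi}).
#' @param a,b frequency coefficients: class \code{i} occurs \code{a[i]*n +
#'   b[i]} times in the n-unit chain.
#' @param nMin smallest valid chain length (default 1).
#' @return a [SymbolicPartition-class].
#' @examples
#' SymbolicPartition(lo = 2, hi = 2, a = 5, b = 0)   # 5n-cycle family
#' @export
SymbolicPartition <- function(lo, hi, a, b, nMin = 1L) {
  cl <- .canonClasses(data.frame(lo = as.integer(lo), hi = as.integer(hi),
                                 a = as.numeric(a), b = as.numeric(b)))
  new("SymbolicPartition", classes = cl, nMin = as.integer(nMin))
}

#' Construct a concrete edge partition
#'
#' @param lo,hi integer degree pairs.
#' @param count positive integer multiplicities.
#' @return an [EdgePartition-class].
#' @examples
#' EdgePartition(lo = c(1, 2), hi = c(2, 2), count = c(2, 3))
#' @export
EdgePartition <- function(lo, hi, count) {
  cl <- .canonClasses(data.frame(lo = as.integer(lo), hi = as.integer(hi),
                                 count = as.numeric(count)))
  new("EdgePartition", classes = cl)
}

.builtinPartitions <- list(
  polyester = list(
    lo = c(1, 1, 1, 2, 2, 3, 4), hi = c(2, 3, 4, 3, 4, 3, 4),
    a  = c(0, 6, 4, 2, 2, 8, 1), b  = c(1, -1, 1, 0, -1, -1, 0)),
  polycarbonate = list(
    lo = c(1, 1, 1, 2, 2, 3, 3, 4), hi = c(2, 3, 4, 2, 3, 3, 4, 4),
    a  = c(0, 5, 6, 2, 8, 6, 2, 2), b  = c(1, 0, 0, 1, -3, 0, 0, 0)))

#' Built-in polymer edge partitions
#'
#' Returns the symbolic degree-based edge partition of the n-unit polyester
#' or polycarbonate chain. Polyester has 7 edge classes summing to
#' \eqn{23n - 1} edges on \eqn{22n} vertices; polycarbonate has 8 classes
#' summing to \eqn{31n - 1} edges on \eqn{29n} vertices.
#'
#' @param polymer \code{"polyester"} or \code{"polycarbonate"}.
#' @return a [SymbolicPartition-class].
#' @examples
#' builtinPartition("polyester")
#' @export
builtinPartition <- function(polymer) {
  if (!is.character(polymer) || length(polymer) != 1L ||
      !polymer %in% names(.builtinPartitions))
    stop("unknown polymer '", paste(polymer, collapse = ","),
         "'; valid identifiers: ",
         paste(names(.builtinPartitions), collapse = ", "))
  p <- .builtinPartitions[[polymer]]
  SymbolicPartition(p$lo, p$hi, p$a, p$b)
}

#' Total edge count of a symbolic partition
#'
#' @param sp a [SymbolicPartition-class].
#' @return a [LinearForm-class]: the sum of all class frequencies.
#' @examples
#' totalEdges(builtinPartition("polycarbonate"))  # 31n - 1
#' @export
totalEdges <- function(sp) {
  stopifnot(is(sp, "SymbolicPartition"))
  LinearForm(sum(sp@classes$a), sum(sp@classes$b))
}

#' Evaluate a symbolic partition at a chain length
#'
#' Substitutes \code{n} into every class frequency; classes evaluating to
#' zero are dropped. Frequencies must evaluate to non-negative integers.
#'
#' @param sp a [SymbolicPartition-class].
#' @param n integer chain length, \code{>= nMin} of the partition.
#' @return an [EdgePartition-class].
#' @examples
#' evaluatePartition(builtinPartition("polyester"), 2)
#' @export
evaluatePartition <- function(sp, n) {
  stopifnot(is(sp, "SymbolicPartition"))
  if (!.isWholeNumber(n) || n < sp@nMin)
    stop("n must be an integer >= ", sp@nMin)
  cl <- sp@classes
  cnt <- cl$a * n + cl$b
  bad <- which(cnt < 0 | !.isWholeNumber(cnt))
  if (length(bad))
    stop(sprintf("class (%d,%d) has invalid frequency %.6g at n = %d",
                 cl$lo[bad[1]], cl$hi[bad[1]], cnt[bad[1]], n))
  keep <- cnt > 0
  if (!any(keep)) stop("partition is empty at n = ", n)
  EdgePartition(cl$lo[keep], cl$hi[keep], round(cnt[keep]))
}

#' Per-degree vertex counts implied by a symbolic partition (handshake check)
#'
#' For every degree \eqn{d}, the number of degree-\eqn{d} vertices must be
#' (total incidences of \eqn{d} over edge classes)\eqn{/d} and an integer
#' at every chain length. A non-integer count at any probed \code{n} means
#' the partition cannot be realized by any graph and is an error.
#'
#' @param sp a [SymbolicPartition-class].
#' @param probe chain lengths to verify integrality at (default
#'   \code{nMin..nMin+19}).
#' @return data.frame with columns \code{degree}, \code{a}, \code{b}: the
#'   vertex-count linear form per degree.
#' @examples
#' degreeConsistency(builtinPartition("polyester"))  # totals 22n
#' @export
degreeConsistency <- function(sp, probe = NULL) {
  stopifnot(is(sp, "SymbolicPartition"))
  if (is.null(probe)) probe <- sp@nMin + 0:19
  cl <- sp@classes
  degs <- sort(unique(c(cl$lo, cl$hi)))
  out <- data.frame(degree = degs, a = NA_real_, b = NA_real_)
  for (i in seq_along(degs)) {
    d <- degs[i]
    inc <- (cl$lo == d) + (cl$hi == d)
    a <- sum(inc * cl$a) / d
    b <- sum(inc * cl$b) / d
    v <- a * probe + b
    j <- which(!.isWholeNumber(v))
    if (length(j))
      stop(sprintf(
        "inconsistent partition: degree %d implies %.6g vertices at n = %d",
        d, v[j[1]], probe[j[1]]))
    out$a[i] <- a; out$b[i] <- b
  }
  out
}

#' Number of edges in a concrete partition
#'
#' @param p an [EdgePartition-class].
#' @return total edge count (sum of class multiplicities).
#' @export
edgeCount <- function(p) {
  stopifnot(is(p, "EdgePartition"))
  sum(p@classes$count)
}

#' Partition classes as a data.frame
#'
#' @param x a [SymbolicPartition-class] or [EdgePartition-class].
#' @return the underlying classes data.frame (copy).
#' @export
partitionClasses <- function(x) {
  stopifnot(is(x, "SymbolicPartition") || is(x, "EdgePartition"))
  x@classes
}

#' Serialize a symbolic partition to JSON
#'
#' @param sp a [SymbolicPartition-class].
#' @param path optional file to write to.
#' @return JSON string (invisibly when \code{path} is given).
#' @examples
#' partitionToJSON(builtinPartition("polyester"))
#' @export
partitionToJSON <- function(sp, path = NULL) {
  stopifnot(is(sp, "SymbolicPartition"))
  obj <- list(classes = sp@classes, n_min = sp@nMin)
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a symbolic partition from JSON
#'
#' @param x JSON string or path to a JSON file produced by
#'   [partitionToJSON()].
#' @return a [SymbolicPartition-class].
#' @export
partitionFromJSON <- function(x) {
  obj <- jsonlite::fromJSON(x)
  cl <- as.data.frame(obj$classes)
  SymbolicPartition(cl$lo, cl$hi, cl$a, cl$b,
                    nMin = if (is.null(obj$n_min)) 1L else obj$n_min)
}

setMethod("show", "SymbolicPartition", function(object) {
  cl <- object@classes
  cat(sprintf("SymbolicPartition: %d classes, edges %s, n >= %d\n",
              nrow(cl), .lfFormat(totalEdges(object)), object@nMin))
  for (i in seq_len(nrow(cl)))
    cat(sprintf("  (%d,%d): %s\n", cl$lo[i], cl$hi[i],
                .lfFormat(LinearForm(cl$a[i], cl$b[i]))))
  invisible(object)
})

setMethod("show", "EdgePartition", function(object) {
  cl <- object@classes
  cat(sprintf("EdgePartition: %d classes, %d edges\n",
              nrow(cl), sum(cl$count)))
  cat(paste(sprintf("  (%d,%d): %d", cl$lo, cl$hi, cl$count),
            collapse = "\n"), "\n")
  invisible(object)
})
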