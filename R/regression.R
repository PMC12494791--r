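#' Fit the logarithmic model Y = a ln X + b
#'
#' Ordinary least squares of \code{y} on \code{log(x)} (natural log), the
#' model used to relate chain entropies to their topological indices. The
#' F-statistic equals \eqn{R^2 (N-2)/(1-R^2)}; for a numerically exact fit
#' \eqn{R^2 = 1}, \eqn{SE = 0}, \eqn{F = \infty} and \eqn{p = 0}.
#'
#' @param x positive regressor values (e.g. index values over n).
#' @param y responses (e.g. entropies).
#' @return a [LogFit-class].
#' @examples
#' sp <- builtinPartition("polyester"); idx <- builtinIndex("M1")
#' fit <- fitLogModel(indexSeries(sp, idx)$value, entropySeries(sp, idx)$entropy)
#' coef(fit)
#' @export
fitLogModel <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  N <- length(x)
  if (N != length(y)) stop("x and y must have equal length")
  if (N < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(x <= 0)) stop("x must be positive and finite")
  lx <- log(x)
  if (diff(range(lx)) == 0) stop("x values are all equal; slope undefined")
  fit <- stats::lm(y ~ lx)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  exactFit <- tss == 0 || rss <= 1e-25 * tss
  if (exactFit) rss <- 0
  R2 <- if (exactFit) 1 else 1 - rss / tss
  SE <- sqrt(rss / (N - 2))
  aSE <- sqrt(rss / (N - 2) / sum((lx - mean(lx))^2))
  if (R2 < 1) {
    Fst <- R2 * (N - 2) / (1 - R2)
    p <- stats::pf(Fst, 1, N - 2, lower.tail = FALSE)
  } else {
    Fst <- Inf; p <- 0
  }
  new("LogFit", a = a, b = b, aSE = aSE,
      R = sign(a) * sqrt(R2), R2 = R2, SE = SE, F = Fst, p = p,
      N = as.integer(N))
}

#' @describeIn fitLogModel slope and intercept of a fit.
#' @param object a [LogFit-class].
#' @param ... unused.
#' @export
setMethod("coef", "LogFit", function(object, ...) {
  c(a = object@a, b = object@b)
})

#' Predict from a logarithmic fit
#'
#' @param object a [LogFit-class].
#' @param newdata positive x value(s).
#' @param ... unused.
#' @return \eqn{a \ln x + b}.
#' @examples
#' fit <- fitLogModel(1:10, 2 * log(1:10) + 1)
#' predict(fit, exp(1))   # 3
#' @export
setMethod("predict", "LogFit", function(object, newdata, ...) {
  x <- as.numeric(newdata)
  if (any(!is.finite(x)) || any(x <= 0)) stop("x must be positive and finite")
  object@a * log(x) + object@b
})

#' Goodness-of-fit statistics of a logarithmic fit
#'
#' @param fit a [LogFit-class].
#' @return named numeric vector: a, b, aSE, R, R2, SE, F, p, N.
#' @export
fitStats <- function(fit) {
  stopifnot(is(fit, "LogFit"))
  c(a = fit@a, b = fit@b, aSE = fit@aSE, R = fit@R, R2 = fit@R2,
    SE = fit@SE, F = fit@F, p = fit@p, N = fit@N)
}

#' Confidence interval for the slope of a logarithmic fit
#'
#' @param fit a [LogFit-class].
#' @param level confidence level (default 0.95).
#' @return numeric length-2 vector, lower and upper bound.
#' @export
slopeConfint <- function(fit, level = 0.95) {
  stopifnot(is(fit, "LogFit"))
  q <- stats::qt(1 - (1 - level) / 2, fit@N - 2)
  c(lower = fit@a - q * fit@aSE, upper = fit@a + q * fit@aSE)
}

setMethod("show", "LogFit", function(object) {
  cat(sprintf(
    "LogFit: y = %.5g ln(x) %s %.5g  (N = %d)\n  R = %.5f, R2 = %.5f, SE = %.3g, F = %.4g, p = %.3g\n",
    object@a, if (object@b < 0) "-" else "+", abs(object@b), object@N,
    object@R, object@R2, object@SE, object@F, object@p))
  invisible(object)
})
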