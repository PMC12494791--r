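# Minimal exact rational arithmetic on integer-valued doubles.
# Numerators/denominators stay far below 2^53 here (degrees <= 8, counts
# linear in n <= a few hundred), so double-held integers are exact and a
# final num/den division is exact whenever the true value is an integer.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.lcm2 <- function(a, b) a / .gcd(a, b) * b

.ratReduce <- function(num, den) {
  stopifnot(den != 0)
  if (den < 0) { num <- -num; den <- -den }
  g <- .gcd(num, den)
  if (g > 1) { num <- num / g; den <- den / g }
  c(unname(num), unname(den))
}

.ratAdd <- function(x, y) {
  .ratReduce(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
}

.ratSub <- function(x, y) .ratAdd(x, c(-y[1], y[2]))

.ratScale <- function(x, k) .ratReduce(k * x[1], x[2])

# sum of counts[i] * num[i]/den[i], exactly
.ratWeightedSum <- function(counts, nums, dens) {
  D <- Reduce(.lcm2, dens, accumulate = FALSE)
  N <- sum(counts * nums * (D / dens))
  .ratReduce(N, D)
}

.isWholeNumber <- function(x, tol = 1e-9) abs(x - round(x)) < tol
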