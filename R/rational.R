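# Minimal exact rational vectors: a list with numeric fields num/den, kept
# reduced with den > 0. Magnitudes in this package stay far below 2^53, so
# doubles hold every intermediate exactly.

rat_gcd <- function(a, b) {
  a <- abs(a)
  b <- abs(b)
  while (any(b != 0)) {
    r <- ifelse(b != 0, a %% b, 0)
    a <- ifelse(b != 0, b, a)
    b <- r
  }
  pmax(a, 1)
}

rat <- function(num, den = 1) {
  if (any(den == 0)) stop("zero denominator in rational value", call. = FALSE)
  k <- if (length(num) == 0) 0 else max(length(num), length(den))
  num <- rep_len(num, k)
  den <- rep_len(den, k)
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn
  den <- den * sgn
  g <- rat_gcd(num, den)
  structure(list(num = num / g, den = den / g), class = "rat")
}

is_rat <- function(x) inherits(x, "rat")

rat_add <- function(a, b) rat(a$num * b$den + b$num * a$den, a$den * b$den)

rat_mul <- function(a, b) rat(a$num * b$num, a$den * b$den)

rat_scale <- function(a, k) rat(a$num * k, a$den)

# exact sum of a rational vector -> length-1 rat
rat_sum <- function(a) {
  num <- 0
  den <- 1
  for (i in seq_along(a$num)) {
    num <- num * a$den[i] + a$num[i] * den
    den <- den * a$den[i]
    g <- rat_gcd(num, den)
    num <- num / g
    den <- den / g
  }
  rat(num, den)
}

rat_numeric <- function(a) a$num / a$den

rat_eq <- function(a, b) a$num == b$num & a$den == b$den

rat_format <- function(a) ifelse(a$den == 1, format(a$num, scientific = FALSE),
                                 paste0(a$num, "/", a$den))

#' @export
print.rat <- function(x, ...) {
  cat(rat_format(x), "\n")
  invisible(x)
}
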