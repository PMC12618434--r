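# Exact rational arithmetic on integer-valued doubles.
#
# Rationals are stored as parallel numerator/denominator vectors of doubles
# holding exact integers. All operations reduce by the gcd and keep the sign
# in the numerator; any intermediate whose magnitude could exceed 2^52 aborts
# rather than silently losing exactness.

RAT_MAX <- 2^52

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  # beyond 2^52 double modulo is unreliable; skip reduction there
  big <- a > RAT_MAX | b > RAT_MAX
  if (any(big)) {
    out <- rep(1, length(a))
    out[!big] <- gcd_int(a[!big], b[!big])
    return(out)
  }
  while (any(b != 0)) {
    t <- b
    b <- a %% b
    b[t == 0] <- 0
    a <- t
  }
  a
}

# integers remain exact in doubles up to 2^53; beyond that, arithmetic
# silently degrades to double precision (only ever reached by boundary
# factors with very large printed coefficients, which are used numerically)
rat_guard <- function(x) {
  if (any(!is.finite(x)))
    stop("non-finite value in rational arithmetic", call. = FALSE)
  x
}

#' Construct an exact rational vector
#'
#' @param num integer-valued numerators.
#' @param den integer-valued denominators (recycled), nonzero.
#' @return an object of class `rat`: a list with fields `num` and `den`,
#'   reduced to lowest terms with positive denominators.
#' @keywords internal
rat <- function(num, den = 1) {
  n <- rat_guard(as.double(num))
  d <- rat_guard(as.double(den))
  if (length(n) == 0) d <- numeric(0)
  if (length(d) != length(n)) {
    m <- max(length(n), length(d))
    n <- rep_len(n, m); d <- rep_len(d, m)
  }
  if (any(d == 0)) stop("zero denominator", call. = FALSE)
  if (any(n != round(n)) || any(d != round(d)))
    stop("rat() requires integer-valued inputs", call. = FALSE)
  s <- ifelse(d < 0, -1, 1)
  n <- n * s; d <- d * s
  g <- gcd_int(n, d)
  g[g == 0] <- 1
  structure(list(num = n / g, den = d / g), class = "rat")
}

rat_len <- function(x) length(x$num)

rat_add <- function(x, y) rat(rat_guard(x$num * y$den + y$num * x$den), rat_guard(x$den * y$den))
rat_sub <- function(x, y) rat(rat_guard(x$num * y$den - y$num * x$den), rat_guard(x$den * y$den))
rat_mul <- function(x, y) {
  # cross-reduce first to delay overflow
  g1 <- gcd_int(x$num, y$den); g1[g1 == 0] <- 1
  g2 <- gcd_int(y$num, x$den); g2[g2 == 0] <- 1
  rat(rat_guard((x$num / g1) * (y$num / g2)), rat_guard((x$den / g2) * (y$den / g1)))
}
rat_div <- function(x, y) {
  if (any(y$num == 0)) stop("division by zero rational", call. = FALSE)
  rat_mul(x, rat(y$den, y$num))
}
rat_neg <- function(x) rat(-x$num, x$den)
rat_abs <- function(x) rat(abs(x$num), x$den)

rat_pow <- function(x, p) {
  stopifnot(length(p) == 1, p == round(p))
  if (p == 0) return(rat(rep(1, rat_len(x))))
  if (p < 0) return(rat_pow(rat_div(rat(rep(1, rat_len(x))), x), -p))
  out <- x
  for (i in seq_len(p - 1)) out <- rat_mul(out, x)
  out
}

rat_eq <- function(x, y) x$num * y$den == y$num * x$den

rat_as_numeric <- function(x) x$num / x$den

rat_slice <- function(x, i) rat(x$num[i], x$den[i])

#' Parse exact rationals from strings like "3", "-7/12"
#' @keywords internal
rat_parse <- function(s) {
  s <- trimws(as.character(s))
  parts <- strsplit(s, "/", fixed = TRUE)
  num <- den <- numeric(length(s))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (!length(p) %in% c(1L, 2L) || anyNA(suppressWarnings(as.numeric(p))))
      stop("cannot parse rational: ", s[i], call. = FALSE)
    v <- as.numeric(p)
    if (any(v != round(v)))
      stop("non-integer literal in rational: ", s[i],
           " (write fractions as p/q)", call. = FALSE)
    num[i] <- v[1]
    den[i] <- if (length(v) == 2) v[2] else 1
  }
  rat(num, den)
}

rat_format <- function(x) {
  ifelse(x$den == 1, format_int(x$num), paste0(format_int(x$num), "/", format_int(x$den)))
}

format_int <- function(v) format(v, scientific = FALSE, trim = TRUE)

#' @export
print.rat <- function(x, ...) {
  cat(paste(rat_format(x), collapse = ", "), "\n")
  invisible(x)
}
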