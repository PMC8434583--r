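#' Exact rational numbers on integer-valued doubles
#'
#' Vectorised exact rational arithmetic used throughout the analytic layer:
#' surface moments, estimation weights, truncation coefficients, and
#' percentage increases are all exact fractions, with floating point entering
#' only when a value is rendered or handed to the mesh layer. Numerators and
#' denominators are stored as integer-valued doubles and every operation
#' checks that intermediates stay below 2^53, the largest range over which
#' double arithmetic on integers is exact; for electrode radii up to 12 all
#' quantities are many orders of magnitude below that bound.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), nonzero; recycled against `num`.
#' @return A `ringlap_rational` vector in lowest terms with positive
#'   denominators.
#' @examples
#' rational(37, 130) + rational(-11, 468)
#' as.numeric(rational(1, 3))
#' @export
rational <- function(num, den = 1) {
  if (length(num) == 0) return(new_rational(numeric(0), numeric(0)))
  n <- max(length(num), length(den))
  num <- rep_len(as.numeric(num), n)
  den <- rep_len(as.numeric(den), n)
  if (any(num != trunc(num)) || any(den != trunc(den))) {
    stop("rational() requires integer-valued numerators and denominators",
         call. = FALSE)
  }
  if (any(den == 0)) stop("zero denominator", call. = FALSE)
  rat_reduce(num, den)
}

new_rational <- function(num, den) {
  structure(list(num = num, den = den), class = "ringlap_rational")
}

#' @rdname rational
#' @param x object to test or coerce.
#' @export
is_rational <- function(x) inherits(x, "ringlap_rational")

.INT_EXACT_MAX <- 2^53

rat_guard <- function(...) {
  vals <- c(...)
  if (any(abs(vals) >= .INT_EXACT_MAX)) {
    stop("exact integer overflow: intermediate exceeds 2^53; ",
         "geometry too large for exact double-based rationals", call. = FALSE)
  }
  invisible(vals)
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b != 0, a %% b, 0)
    a <- t
  }
  a
}

rat_reduce <- function(num, den) {
  rat_guard(num, den)
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn
  den <- den * sgn
  g <- gcd2(num, den)
  g[g == 0] <- 1
  new_rational(num / g, den / g)
}

#' @export
length.ringlap_rational <- function(x) length(x$num)

#' @export
`[.ringlap_rational` <- function(x, i) new_rational(x$num[i], x$den[i])

#' @export
format.ringlap_rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%.0f", x$num),
         sprintf("%.0f/%.0f", x$num, x$den))
}

#' @export
print.ringlap_rational <- function(x, ...) {
  cat("<rational> ", paste(format(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.ringlap_rational <- function(x, ...) format(x)

#' @export
as.double.ringlap_rational <- function(x, ...) x$num / x$den

#' @export
abs.ringlap_rational <- function(x) new_rational(abs(x$num), x$den)

as_rat <- function(x) {
  if (is_rational(x)) x else rational(x)
}

# lcm-denominator addition/subtraction keeps intermediates minimal
rat_addsub <- function(a, b, sign) {
  g <- gcd2(a$den, b$den)
  g[g == 0] <- 1
  fa <- b$den / g
  fb <- a$den / g
  rat_guard(a$num * fa, b$num * fb, a$den * fa)
  rat_reduce(a$num * fa + sign * b$num * fb, a$den * fa)
}

#' @export
Ops.ringlap_rational <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(new_rational(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rationals", call. = FALSE)
  }
  a <- as_rat(e1); b <- as_rat(e2)
  switch(.Generic,
    "+" = rat_addsub(a, b, 1),
    "-" = rat_addsub(a, b, -1),
    "*" = {
      # cross-reduce before multiplying to keep intermediates small
      g1 <- gcd2(a$num, b$den); g1[g1 == 0] <- 1
      g2 <- gcd2(b$num, a$den); g2[g2 == 0] <- 1
      rat_reduce((a$num / g1) * (b$num / g2), (a$den / g2) * (b$den / g1))
    },
    "/" = {
      if (any(b$num == 0)) stop("division by zero rational", call. = FALSE)
      g1 <- gcd2(a$num, b$num); g1[g1 == 0] <- 1
      g2 <- gcd2(b$den, a$den); g2[g2 == 0] <- 1
      rat_reduce((a$num / g1) * (b$den / g2), (a$den / g2) * (b$num / g1))
    },
    "==" = a$num * b$den == b$num * a$den,
    "!=" = a$num * b$den != b$num * a$den,
    "<"  = { rat_guard(a$num * b$den, b$num * a$den); a$num * b$den < b$num * a$den },
    ">"  = { rat_guard(a$num * b$den, b$num * a$den); a$num * b$den > b$num * a$den },
    "<=" = { rat_guard(a$num * b$den, b$num * a$den); a$num * b$den <= b$num * a$den },
    ">=" = { rat_guard(a$num * b$den, b$num * a$den); a$num * b$den >= b$num * a$den },
    stop(.Generic, " not defined for rationals", call. = FALSE)
  )
}

#' Sum a rational vector exactly
#'
#' @param x a `ringlap_rational` vector.
#' @return A length-1 `ringlap_rational`.
#' @export
rat_sum <- function(x) {
  stopifnot(is_rational(x))
  out <- rational(0)
  for (i in seq_len(length(x))) out <- out + x[i]
  out
}

#' Render a rational as a decimal string, rounding half away from zero
#'
#' Table output uses half-up rounding (3 decimals for truncation
#' coefficients, 2 for percentages). The rounding is carried out in integer
#' arithmetic on the exact fraction, so no double-rounding artefacts can
#' occur at the printed precision.
#'
#' @param x a `ringlap_rational` vector.
#' @param digits number of decimal places.
#' @return Character vector of fixed-point decimals.
#' @examples
#' rat_decimal(rational(163, 36), 3)  # "4.528"
#' @export
rat_decimal <- function(x, digits = 3) {
  stopifnot(is_rational(x), digits >= 0)
  scale <- 10^digits
  # digit-wise long division so arbitrarily large fractions never overflow:
  # q accumulates floor(|num| / den * 10^digits), r the running remainder
  n <- abs(x$num)
  d <- x$den
  q <- n %/% d
  r <- n %% d
  for (i in seq_len(digits)) {
    r10 <- r * 10
    q <- q * 10 + r10 %/% d
    r <- r10 %% d
  }
  q <- q + (2 * r >= d)  # round half away from zero
  rat_guard(q)
  sprintf("%s%.*f", ifelse(x$num < 0 & q != 0, "-", ""), digits, q / scale)
}

#' @rdname rat_decimal
#' @export
rat_round <- function(x, digits = 3) as.numeric(rat_decimal(x, digits))
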