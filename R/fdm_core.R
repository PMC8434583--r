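#' Exact even-power radial moment of a recording surface
#'
#' Truncating the Taylor expansion of the potential averaged over a circle of
#' radius `r` (in intervals) leaves terms proportional to `r^(2k)`. The
#' moment of a recording surface is the mean of `r^(2k)` over the
#' integer-radius circles it covers, computed exactly.
#'
#' @param circles integer vector of circle radii (intervals), e.g. one
#'   element of [surface_circles()].
#' @param k moment order, integer >= 1.
#' @return A length-1 [rational()].
#' @examples
#' surface_moment(0:1, 1)    # 1/2
#' surface_moment(4:9, 1)    # 271/6
#' @export
surface_moment <- function(circles, k) {
  if (length(k) != 1 || k < 1 || k != trunc(k)) {
    stop("moment order k must be a single integer >= 1", call. = FALSE)
  }
  if (length(circles) == 0) stop("empty circle set", call. = FALSE)
  pw <- as.numeric(circles)^(2 * k)
  rat_guard(pw)
  rational(sum(pw), length(circles))
}

#' Bipolar-difference moments of a configuration
#'
#' For each ring j and order k, the difference `D[j,k] = m_k(ring j) -
#' m_k(disc)` is the coefficient multiplying the k-th Laplacian-series term
#' in the bipolar difference between the ring potential and the central-disc
#' potential (the centre potential cancels in the difference).
#'
#' @param config a [cre_config()].
#' @param orders integer vector of moment orders.
#' @return A list with `num` and `den` matrices of dimension
#'   `length(orders)` x `n_rings` holding exact fractions, plus the orders.
#' @keywords internal
difference_moments <- function(config, orders) {
  config <- as_cre_config(config)
  circ <- surface_circles(config)
  disc <- circ[[1]]
  D <- matrix(list(), nrow = length(orders), ncol = config$n_rings)
  for (ik in seq_along(orders)) {
    md <- surface_moment(disc, orders[ik])
    for (j in seq_len(config$n_rings)) {
      D[[ik, j]] <- surface_moment(circ[[j + 1]], orders[ik]) - md
    }
  }
  attr(D, "orders") <- orders
  D
}

# Exact Gaussian elimination with partial (first nonzero) pivoting on a
# matrix of length-1 rationals; A is a list-matrix, b a list of rationals.
rat_solve <- function(A, b) {
  n <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == n)
  A <- A; x <- b
  for (col in seq_len(n)) {
    piv <- col - 1 + which(vapply(col:n, function(r) A[[r, col]]$num != 0, TRUE))[1]
    if (is.na(piv)) {
      mat <- apply(A, c(1, 2), function(e) format(e[[1]]))
      stop("singular moment matrix:\n",
           paste(apply(mat, 1, paste, collapse = "  "), collapse = "\n"),
           call. = FALSE)
    }
    if (piv != col) {
      tmp <- A[col, ]; A[col, ] <- A[piv, ]; A[piv, ] <- tmp
      tmp <- x[[col]]; x[[col]] <- x[[piv]]; x[[piv]] <- tmp
    }
    for (r in setdiff(seq_len(n), col)) {
      if (A[[r, col]]$num == 0) next
      f <- A[[r, col]] / A[[col, col]]
      for (c2 in seq_len(n)) A[[r, c2]] <- A[[r, c2]] - f * A[[col, c2]]
      x[[r]] <- x[[r]] - f * x[[col]]
    }
  }
  lapply(seq_len(n), function(i) x[[i]] / A[[i, i]])
}

#' Solve for the exact surface-Laplacian estimation weights
#'
#' The estimate is a linear combination of the bipolar differences (ring
#' potential minus central-disc potential) divided by the squared interval
#' length h. The weights are the exact rational solution of the system that
#' cancels the difference moments of orders 2..n_rings (for a TCRE, the
#' 4th-order truncation term) while normalising the order-1 sum to 4, so
#' that the first Taylor term — whose circle-average coefficient is r^2/4 —
#' contributes exactly one unit of the Laplacian.
#'
#' @param config a [cre_config()] (or boundary vector).
#' @return A `cre_weights` object: fields `w` (rational vector, one weight
#'   per ring, lowest terms), `config`, `order_cancelled`.
#' @examples
#' solve_weights(named_config("CIRD"))     # 37/130, -11/468
#' solve_weights(named_config("OPTIMAL"))  # 952/1227, -6/409
#' @export
solve_weights <- function(config) {
  config <- as_cre_config(config)
  n <- config$n_rings
  D <- difference_moments(config, seq_len(n))
  b <- c(list(rational(4)), rep(list(rational(0)), n - 1))
  w <- rat_solve(D, b)
  wv <- new_rational(vapply(w, function(r) r$num, 1),
                     vapply(w, function(r) r$den, 1))
  structure(
    list(w = wv, config = config, order_cancelled = 2 * n),
    class = "cre_weights")
}

#' @export
print.cre_weights <- function(x, ...) {
  cat(sprintf("<cre_weights> %s: (%s)\n", format(x$config),
              paste(format(x$w), collapse = ", ")))
  invisible(x)
}

#' Lowest remaining truncation-term coefficient
#'
#' After cancelling orders up to twice the number of rings, the lowest
#' surviving Taylor term of the weighted bipolar-difference sum has order
#' `2*(n_rings + 1)` (6 for a TCRE). Its absolute coefficient —
#' `|sum_j w_j D[j, n_rings + 1]| / (2 * (2*(n_rings + 1))!)`, divisor 1440
#' for a TCRE — is the figure of merit ranking configurations: the ratio of
#' two configurations' coefficients predicts the ratio of their Laplacian
#' estimation errors.
#'
#' @param config a [cre_config()], boundary vector, or `cre_weights`.
#' @return A `cre_truncation` object: `value` (exact non-negative rational),
#'   `order`, `config`.
#' @examples
#' truncation_coefficient(named_config("CIRD"))  # 163/36 = 4.528
#' @export
truncation_coefficient <- function(config) {
  wts <- if (inherits(config, "cre_weights")) config else solve_weights(config)
  cfg <- wts$config
  n <- cfg$n_rings
  ord <- 2 * (n + 1)
  D <- difference_moments(cfg, n + 1)
  acc <- rational(0)
  for (j in seq_len(n)) acc <- acc + wts$w[j] * D[[1, j]]
  structure(
    list(value = abs(acc) / rational(2 * factorial(ord)),
         order = ord, config = cfg),
    class = "cre_truncation")
}

#' @export
print.cre_truncation <- function(x, ...) {
  cat(sprintf("<cre_truncation> %s: |c%d| = %s = %s\n", format(x$config),
              x$order, format(x$value), rat_decimal(x$value, 3)))
  invisible(x)
}

#' @export
as.double.cre_truncation <- function(x, ...) as.numeric(x$value)

#' Surface-Laplacian estimate from recording-surface potentials
#'
#' Applies the estimation weights to measured (or simulated) surface
#' potentials: `(sum_j w_j (P_j - P_disc)) / h^2`, the finite-difference
#' estimate of the tangential Laplacian of the potential at the electrode
#' centre. Note the planar-mesh validation layer ([estimate_map()]) reports
#' the opposite sign so that its maps are directly comparable to the dipole
#' field's conventional Laplacian (see that help page).
#'
#' @param weights a `cre_weights` object from [solve_weights()].
#' @param potentials numeric vector of surface potentials, disc first, then
#'   rings outward (same units, e.g. volts).
#' @param h physical interval length (electrode radius / number of
#'   intervals), in the length unit of the Laplacian's denominator.
#' @return The Laplacian estimate (potential units per length squared).
#' @examples
#' w <- solve_weights(named_config("OPTIMAL"))
#' # potentials of v = x^2 + y^2 averaged over each surface, h = 1:
#' p <- vapply(surface_circles(w$config), function(rs) mean(rs^2), 1)
#' laplacian_estimate(w, p, 1)  # exactly 4
#' @export
laplacian_estimate <- function(weights, potentials, h) {
  stopifnot(inherits(weights, "cre_weights"))
  n <- weights$config$n_rings
  if (length(potentials) != n + 1) {
    stop("need one potential per recording surface (disc first): expected ",
         n + 1, ", got ", length(potentials), call. = FALSE)
  }
  if (length(h) != 1 || h <= 0) stop("h must be a positive scalar", call. = FALSE)
  wn <- as.numeric(weights$w)
  sum(wn * (potentials[-1] - potentials[1])) / h^2
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the exact estimation weights
#'
#' @param x a `cre_weights` object from [solve_weights()].
#' @param ... unused.
#' @return One row per ring: exact fraction and decimal weight.
#' @export
tidy.cre_weights <- function(x, ...) {
  tibble::tibble(
    ring = seq_len(x$config$n_rings),
    weight_frac = format(x$w),
    weight = as.numeric(x$w))
}

#' One-row summary of a weight solution
#'
#' Geometry, cancelled order, and the lowest remaining truncation
#' coefficient of a `cre_weights` fit.
#'
#' @param x a `cre_weights` object from [solve_weights()].
#' @param ... unused.
#' @export
glance.cre_weights <- function(x, ...) {
  tc <- truncation_coefficient(x)
  tibble::tibble(
    config = format(x$config),
    n_rings = x$config$n_rings,
    outer_radius = x$config$outer_radius,
    order_cancelled = x$order_cancelled,
    truncation_order = tc$order,
    truncation_coefficient = as.numeric(tc$value),
    truncation_frac = format(tc$value))
}
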