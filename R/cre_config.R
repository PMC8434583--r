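#' Concentric ring electrode geometry on an integer grid
#'
#' Under the finite dimensions model (FDM) the electrode radius is divided
#' into equal intervals and every recording surface — the central disc and
#' each concentric ring — occupies a whole number of intervals. A tripolar
#' electrode (TCRE) has a disc and two rings, so its geometry is fixed by the
#' integer boundaries `(disc, a1, b1, ..., an, bn)` with `bn` the outer
#' radius. Boundaries must strictly increase, which guarantees ring widths
#' and inter-surface gaps of at least one interval.
#'
#' @param disc_radius integer outer boundary of the central disc, in grid
#'   intervals (>= 1).
#' @param rings list of length-2 integer vectors `c(inner, outer)`, one per
#'   ring, ordered outward.
#' @return A `cre_config` object with fields `disc_radius`, `rings`,
#'   `n_rings`, `outer_radius`.
#' @examples
#' cre_config(1, list(c(2, 3), c(4, 9)))  # the optimal radius-9 TCRE
#' @export
cre_config <- function(disc_radius, rings) {
  if (!is.list(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) as.numeric(r))
  if (any(vapply(rings, length, 1L) != 2)) {
    stop("each ring must be c(inner, outer)", call. = FALSE)
  }
  bounds <- c(as.numeric(disc_radius), unlist(rings))
  if (any(bounds != trunc(bounds))) {
    stop("boundaries must be integers (grid intervals)", call. = FALSE)
  }
  if (disc_radius < 1) stop("disc_radius must be >= 1", call. = FALSE)
  bad <- which(diff(bounds) <= 0)
  if (length(bad)) {
    stop(sprintf(
      "boundaries must strictly increase: %g >= %g at position %d",
      bounds[bad[1]], bounds[bad[1] + 1], bad[1]), call. = FALSE)
  }
  structure(
    list(disc_radius = bounds[1],
         rings = rings,
         n_rings = length(rings),
         outer_radius = bounds[length(bounds)]),
    class = "cre_config")
}

#' @rdname cre_config
#' @param x object to test, coerce or print.
#' @export
is_cre_config <- function(x) inherits(x, "cre_config")

#' @rdname cre_config
#' @param ... unused.
#' @export
format.cre_config <- function(x, ...) {
  paste(c(x$disc_radius,
          vapply(x$rings, function(r) sprintf("%g-%g", r[1], r[2]), "")),
        collapse = "|")
}

#' @export
print.cre_config <- function(x, ...) {
  cat(sprintf("<cre_config> %s (disc + %d ring%s, outer radius %g)\n",
              format(x), x$n_rings, if (x$n_rings == 1) "" else "s",
              x$outer_radius))
  invisible(x)
}

#' @rdname cre_config
#' @param boundaries numeric vector `(disc, a1, b1, ..., an, bn)`.
#' @export
as_cre_config <- function(boundaries) {
  if (is_cre_config(boundaries)) return(boundaries)
  b <- as.numeric(boundaries)
  if (length(b) < 3 || length(b) %% 2 == 0) {
    stop("boundaries must be (disc, a1, b1, ..., an, bn)", call. = FALSE)
  }
  cre_config(b[1], split(b[-1], rep(seq_len((length(b) - 1) / 2), each = 2)))
}

config_boundaries <- function(config) {
  c(config$disc_radius, unlist(config$rings))
}

#' Integer-radius circles covered by each recording surface
#'
#' The FDM surface potential of each recording surface is the unweighted mean
#' of the average potentials on the integer-radius concentric circles it
#' covers; the central disc includes the centre point (radius 0).
#'
#' @param config a [cre_config()].
#' @return A list of integer vectors, the first for the disc, then one per
#'   ring outward.
#' @examples
#' surface_circles(cre_config(1, list(c(2, 3), c(4, 9))))
#' @export
surface_circles <- function(config) {
  config <- as_cre_config(config)
  c(list(0:config$disc_radius),
    lapply(config$rings, function(r) seq(r[1], r[2])))
}

#' Reference TCRE configurations at outer radius 9
#'
#' The constant inter-ring distances (CIRD) and linearly increasing
#' inter-ring distances (LIIRD) configurations have disc and ring widths of
#' one interval each, with gaps 3/3 and 2/4 intervals respectively; the
#' optimal configuration keeps all surfaces at minimal distance and gives the
#' whole remaining area to the outer ring.
#'
#' @param name one of `"CIRD"`, `"LIIRD"`, `"OPTIMAL"` (case-insensitive).
#' @param outer_radius electrode radius in intervals; only 9 is defined.
#' @return A [cre_config()].
#' @examples
#' named_config("CIRD")
#' @export
named_config <- function(name, outer_radius = 9) {
  if (outer_radius != 9) {
    stop("named configurations are defined for outer_radius = 9", call. = FALSE)
  }
  switch(toupper(name),
    CIRD = cre_config(1, list(c(4, 5), c(8, 9))),
    LIIRD = cre_config(1, list(c(3, 4), c(8, 9))),
    OPTIMAL = cre_config(1, list(c(2, 3), c(4, 9))),
    stop("unknown configuration '", name,
         "'; valid names: CIRD, LIIRD, OPTIMAL", call. = FALSE))
}
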