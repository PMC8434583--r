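#' Current dipole in a homogeneous medium
#'
#' The validation field is a unit current dipole at depth `depth_cm` below
#' the measurement plane z = 0, oriented along +Z, in a homogeneous medium
#' of conductivity `sigma`. With distances in cm, sigma entered as 7.14
#' (mS/cm, emulating biological tissue) and a unit moment, potentials read
#' as volts and Laplacians as V/cm^2 — the convention that reproduces an
#' on-axis Laplacian of 0.825 mV/cm^2 at 3 cm depth.
#'
#' @param depth_cm dipole depth below the plane, cm (> 0).
#' @param sigma medium conductivity (default 7.14).
#' @param moment dipole moment vector `c(px, py, pz)` (default unit +Z).
#' @param xy dipole (x, y) position in the plane, cm.
#' @return A `dipole_model` object.
#' @examples
#' dipole_model(3)
#' @export
dipole_model <- function(depth_cm, sigma = 7.14, moment = c(0, 0, 1),
                         xy = c(0, 0)) {
  stopifnot(depth_cm > 0, sigma > 0, length(moment) == 3, length(xy) == 2)
  structure(
    list(location = c(xy[1], xy[2], -depth_cm), depth_cm = depth_cm,
         moment = as.numeric(moment), sigma = sigma),
    class = "dipole_model")
}

#' @export
print.dipole_model <- function(x, ...) {
  cat(sprintf(
    "<dipole_model> depth %.3g cm at (%.3g, %.3g), moment (%g, %g, %g), sigma %.3g\n",
    x$depth_cm, x$location[1], x$location[2],
    x$moment[1], x$moment[2], x$moment[3], x$sigma))
  invisible(x)
}

dipole_displacement <- function(dipole, x, y, z) {
  list(dx = x - dipole$location[1],
       dy = y - dipole$location[2],
       dz = z - dipole$location[3])
}

#' Electric potential of a dipole
#'
#' `v = (1/(4 pi sigma)) * ((rp - r) . p) / |rp - r|^3` at observation
#' points `(x, y, z)`; vectorised over the observation coordinates.
#'
#' @param dipole a [dipole_model()].
#' @param x,y,z observation coordinates, cm (default on the plane z = 0).
#' @return Potential in volts, same shape as `x`.
#' @examples
#' dipole_potential(dipole_model(3), 0, 0)  # 1/(4 pi 7.14 * 9)
#' @export
dipole_potential <- function(dipole, x, y, z = 0) {
  d <- dipole_displacement(dipole, x, y, z)
  r2 <- d$dx^2 + d$dy^2 + d$dz^2
  if (any(r2 == 0)) stop("observation point coincides with the dipole", call. = FALSE)
  p <- dipole$moment
  (d$dx * p[1] + d$dy * p[2] + d$dz * p[3]) / (4 * pi * dipole$sigma * r2^1.5)
}

#' Analytical Laplacian of the dipole potential
#'
#' The closed-form second spatial derivative used as the reference map:
#' `(3/(4 pi sigma)) * (5 (zp - z)^2 ((rp - r).p) / |rp - r|^7 -
#' ((rp - r).p + 2 (zp - z) pz) / |rp - r|^5)`. For the source-free
#' half-space this equals the second z-derivative of the potential, i.e.
#' minus its tangential (x, y) Laplacian, the conventional sign under which
#' a superficial source produces a positive Laplacian peak; on the dipole
#' axis it reduces to `6 / (4 pi sigma depth^4)`.
#'
#' @inheritParams dipole_potential
#' @return Laplacian in V/cm^2, same shape as `x`.
#' @examples
#' dipole_laplacian(dipole_model(3), 0, 0) * 1000  # 0.825 mV/cm^2
#' @export
dipole_laplacian <- function(dipole, x, y, z = 0) {
  d <- dipole_displacement(dipole, x, y, z)
  r2 <- d$dx^2 + d$dy^2 + d$dz^2
  if (any(r2 == 0)) stop("observation point coincides with the dipole", call. = FALSE)
  p <- dipole$moment
  dot <- d$dx * p[1] + d$dy * p[2] + d$dz * p[3]
  3 / (4 * pi * dipole$sigma) *
    (5 * d$dz^2 * dot / r2^3.5 - (dot + 2 * d$dz * p[3]) / r2^2.5)
}
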