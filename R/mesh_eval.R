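#' Planar evaluation mesh for the dipole validation
#'
#' A square mesh of `n_nodes` x `n_nodes` points with spacing 0.25/9 cm
#' (approximately 0.278 mm) covering roughly 20 cm x 20 cm. The spacing is
#' exactly one ninth of a 0.25 cm electrode interval, so every tested
#' electrode diameter from 0.5 to 5 cm places all of its circle sample
#' points on mesh nodes. The dipole sits below `dipole_node` (1-based);
#' `dipole_offset` shifts it by a fraction of the spacing in x and y to
#' model sub-grid centring (default 0: a node lies exactly on-axis).
#'
#' @param n_nodes nodes per side (default 700).
#' @param spacing node spacing, cm (default 0.25/9).
#' @param dipole_node integer `c(i, j)` node index the dipole is projected
#'   to (default `c(350, 350)`).
#' @param dipole_offset fraction of `spacing` added to the dipole's x and y
#'   (default 0).
#' @return A `mesh_spec` object.
#' @export
mesh_spec <- function(n_nodes = 700, spacing = 0.25 / 9,
                      dipole_node = c(350, 350), dipole_offset = 0) {
  stopifnot(spacing > 0, length(dipole_node) == 2,
            all(dipole_node >= 1), all(dipole_node <= n_nodes))
  structure(
    list(n_nodes = as.integer(n_nodes), spacing = spacing,
         dipole_node = as.integer(dipole_node),
         dipole_offset = dipole_offset),
    class = "mesh_spec")
}

#' @export
print.mesh_spec <- function(x, ...) {
  cat(sprintf(
    "<mesh_spec> %d x %d nodes, spacing %.4g cm (side %.3g cm), dipole under node (%d, %d)%s\n",
    x$n_nodes, x$n_nodes, x$spacing, (x$n_nodes - 1) * x$spacing,
    x$dipole_node[1], x$dipole_node[2],
    if (x$dipole_offset != 0) sprintf(" + %.3g spacing offset", x$dipole_offset) else ""))
  invisible(x)
}

mesh_axis <- function(mesh) (seq_len(mesh$n_nodes) - 1) * mesh$spacing

mesh_dipole <- function(mesh, depth_cm, sigma = 7.14) {
  ax <- mesh_axis(mesh)
  off <- mesh$dipole_offset * mesh$spacing
  dipole_model(depth_cm, sigma = sigma,
               xy = c(ax[mesh$dipole_node[1]] + off,
                      ax[mesh$dipole_node[2]] + off))
}

#' Field grids over the mesh
#'
#' Evaluate the dipole potential (volts) or the analytical Laplacian
#' (V/cm^2) at every node of the mesh plane z = 0.
#'
#' @param mesh a [mesh_spec()].
#' @param dipole a [dipole_model()], typically from a depth via
#'   `laplacian_grid(mesh, depth_cm = 3)`.
#' @param depth_cm convenience: build the dipole at this depth below the
#'   mesh's dipole node (ignored when `dipole` is given).
#' @param sigma conductivity used with `depth_cm`.
#' @return An `n_nodes` x `n_nodes` matrix; rows index x, columns y.
#' @examples
#' m <- mesh_spec(n_nodes = 101, dipole_node = c(51, 51))
#' max(laplacian_grid(m, depth_cm = 3))
#' @export
potential_grid <- function(mesh, dipole = NULL, depth_cm = NULL, sigma = 7.14) {
  dipole <- dipole %||% mesh_dipole(mesh, depth_cm, sigma)
  ax <- mesh_axis(mesh)
  dipole_potential(dipole,
                   outer(ax, rep(1, mesh$n_nodes)),
                   outer(rep(1, mesh$n_nodes), ax))
}

#' @rdname potential_grid
#' @export
laplacian_grid <- function(mesh, dipole = NULL, depth_cm = NULL, sigma = 7.14) {
  dipole <- dipole %||% mesh_dipole(mesh, depth_cm, sigma)
  ax <- mesh_axis(mesh)
  dipole_laplacian(dipole,
                   outer(ax, rep(1, mesh$n_nodes)),
                   outer(rep(1, mesh$n_nodes), ax))
}

#' Electrode-to-mesh alignment
#'
#' An electrode of diameter `diameter_cm` has interval length
#' `h = diameter/18` cm (radius of nine intervals); on the default mesh
#' this is `2 * diameter_cm` grid steps per interval, which must be a whole
#' number for the circle sample points to fall on nodes.
#'
#' @param mesh a [mesh_spec()].
#' @param diameter_cm electrode outer diameter, cm.
#' @return A list with `steps` (grid steps per interval), `h` (cm), and
#'   `margin` (grid margin of the valid region, `9 * steps`).
#' @keywords internal
electrode_alignment <- function(mesh, diameter_cm) {
  h <- diameter_cm / 18
  steps <- h / mesh$spacing
  if (abs(steps - round(steps)) > 1e-9) {
    stop(sprintf(
      "diameter %g cm is not mesh-aligned: interval %g cm is %.4g grid steps",
      diameter_cm, h, steps), call. = FALSE)
  }
  steps <- as.integer(round(steps))
  if (steps < 1) stop("electrode smaller than one grid step", call. = FALSE)
  list(steps = steps, h = h, margin = 9L * steps)
}

valid_indices <- function(mesh, margin) {
  if (2 * margin >= mesh$n_nodes) {
    stop("electrode too large for the mesh: no valid region", call. = FALSE)
  }
  (margin + 1):(mesh$n_nodes - margin)
}

#' Four-point circle potential
#'
#' The mean of the grid values at the four axis-aligned points
#' `(+-radius_steps, 0)` and `(0, +-radius_steps)` relative to
#' `center_node` — the discretisation of the circle-average potential used
#' on the mesh.
#'
#' @param grid matrix from [potential_grid()].
#' @param center_node integer `c(i, j)` (1-based).
#' @param radius_steps circle radius in grid steps (0 returns the centre
#'   value).
#' @return The mean potential at the four points.
#' @export
circle_potential <- function(grid, center_node, radius_steps) {
  i <- center_node[1]; j <- center_node[2]; r <- radius_steps
  if (r == 0) return(grid[i, j])
  if (i - r < 1 || j - r < 1 || i + r > nrow(grid) || j + r > ncol(grid)) {
    stop("circle sample point outside the grid", call. = FALSE)
  }
  (grid[i - r, j] + grid[i + r, j] + grid[i, j - r] + grid[i, j + r]) / 4
}

# Per-circle weights of the full estimate: the estimate is a fixed linear
# combination of the ten circle potentials r = 0..9. Disc circles carry
# +(sum w)/(disc size); ring-j circles carry -w_j/(ring width). The signs
# implement the disc-minus-ring convention matching dipole_laplacian().
circle_coefficients <- function(weights) {
  cfg <- weights$config
  if (cfg$outer_radius != 9) {
    stop("mesh evaluation expects a radius-9 (nine-interval) configuration",
         call. = FALSE)
  }
  circ <- surface_circles(cfg)
  wn <- as.numeric(weights$w)
  coef <- numeric(10)
  coef[circ[[1]] + 1] <- sum(wn) / length(circ[[1]])
  for (j in seq_len(cfg$n_rings)) {
    coef[circ[[j + 1]] + 1] <- -wn[j] / length(circ[[j + 1]])
  }
  coef
}

# Shifted-submatrix circle maps over the valid region: list C[[r+1]] for
# r = 0..9 of matrices of the 4-point circle potentials at radius r*steps.
circle_maps <- function(grid, idx, steps) {
  sub <- function(di, dj) grid[idx + di, idx + dj, drop = FALSE]
  lapply(0:9, function(r) {
    rho <- r * steps
    if (rho == 0) sub(0L, 0L)
    else (sub(-rho, 0L) + sub(rho, 0L) + sub(0L, -rho) + sub(0L, rho)) / 4
  })
}

#' Laplacian-estimate map of an electrode over the mesh
#'
#' At every node far enough from the mesh edge, forms the ten 4-point
#' circle potentials at radii `r * steps` (r = 0..9), averages them into
#' the three recording-surface potentials of the configuration, and
#' combines the two bipolar differences with the estimation weights divided
#' by h^2. Maps are reported in the sign convention of
#' [dipole_laplacian()] (disc minus ring), so estimate and analytical maps
#' are directly comparable; applied to a synthetic field `v = x^2 + y^2`
#' the map is therefore identically -4 (minus the tangential Laplacian).
#'
#' @param grid potential matrix from [potential_grid()] (or any synthetic
#'   field on the mesh).
#' @param mesh the [mesh_spec()] the grid was built on.
#' @param weights a `cre_weights` from [solve_weights()] for a radius-9
#'   configuration (a `cre_config` is accepted and solved).
#' @param diameter_cm electrode outer diameter, cm (mesh-aligned).
#' @return A matrix over the valid region (side `n_nodes - 18 * steps`)
#'   with attributes `valid` (the node index range) and `h`.
#' @export
estimate_map <- function(grid, mesh, weights, diameter_cm) {
  if (!inherits(weights, "cre_weights")) weights <- solve_weights(weights)
  al <- electrode_alignment(mesh, diameter_cm)
  idx <- valid_indices(mesh, al$margin)
  coef <- circle_coefficients(weights)
  cm <- circle_maps(grid, idx, al$steps)
  est <- matrix(0, length(idx), length(idx))
  for (r in 0:9) est <- est + coef[r + 1] * cm[[r + 1]]
  est <- est / al$h^2
  attr(est, "valid") <- range(idx)
  attr(est, "h") <- al$h
  est
}

#' Comparison measures between an estimate map and the analytical map
#'
#' * `max_amp`: maximum absolute Laplacian over the valid region (V/cm^2) —
#'   sensitivity.
#' * `nsg_pct`: normalized spatial gradient at the dipole node — the mean
#'   over four cross-shaped displacements of `d_cm` of
#'   `|L(center) - L(displaced)| / L(center)`, in percent — spatial
#'   resolution.
#' * `re_pct`: relative error `sqrt(sum((L - Lhat)^2) / sum(L^2))` over the
#'   valid region, percent.
#' * `nme_pct`: normalized maximum error `max|L - Lhat| / max|L|`, percent.
#' * `max_err`: unnormalised maximum absolute error (V/cm^2).
#'
#' @param est estimate map from [estimate_map()] (or the analytical map
#'   itself restricted to a valid region, for reference rows).
#' @param ana full analytical Laplacian grid from [laplacian_grid()].
#' @param mesh the [mesh_spec()].
#' @param d_cm NSG displacement, cm (default 0.5, the smallest tested
#'   electrode diameter; must be a whole number of grid steps).
#' @return A one-row tibble with the five measures.
#' @export
laplacian_measures <- function(est, ana, mesh, d_cm = 0.5) {
  vr <- attr(est, "valid")
  if (is.null(vr)) stop("estimate map lacks a valid-region attribute", call. = FALSE)
  idx <- vr[1]:vr[2]
  ana_v <- ana[idx, idx]
  kd <- d_cm / mesh$spacing
  if (abs(kd - round(kd)) > 1e-9) {
    stop("NSG displacement is not a whole number of grid steps", call. = FALSE)
  }
  tibble::tibble(
    max_amp = max(abs(est)),
    nsg_pct = 100 * map_nsg(est, mesh$dipole_node - vr[1] + 1L, as.integer(round(kd))),
    re_pct = 100 * sqrt(sum((ana_v - est)^2) / sum(ana_v^2)),
    nme_pct = 100 * max(abs(ana_v - est)) / max(abs(ana_v)),
    max_err = max(abs(ana_v - est)))
}

map_nsg <- function(map, center, k) {
  i <- center[1]; j <- center[2]
  if (i - k < 1 || j - k < 1 || i + k > nrow(map) || j + k > ncol(map)) {
    stop("NSG displacement leaves the valid region", call. = FALSE)
  }
  l0 <- map[i, j]
  if (l0 == 0) stop("NSG undefined: zero Laplacian at the centre", call. = FALSE)
  mean(abs(l0 - c(map[i - k, j], map[i + k, j], map[i, j - k], map[i, j + k]))) / l0
}

with_valid <- function(map, idx) {
  attr(map, "valid") <- range(idx)
  map
}

#' Sweep measures over configurations, diameters, and depths
#'
#' Runs the full mesh validation: for each dipole depth it builds the
#' potential and analytical-Laplacian grids once, then for each electrode
#' diameter forms the shared circle maps and evaluates every configuration's
#' estimate, returning the comparison measures in a tidy table. Rows with
#' `config == "analytical"` carry the reference map's own measures
#' (`re_pct`/`nme_pct` are 0 by definition and reported as NA).
#'
#' @param configs named list of configurations (`cre_config` or
#'   `cre_weights`); default the three reference TCREs.
#' @param diameters_cm electrode diameters, cm.
#' @param depths_cm dipole depths, cm.
#' @param mesh a [mesh_spec()].
#' @param sigma conductivity.
#' @param include_analytical add the analytical reference rows.
#' @return A tibble `(config, diameter_cm, depth_cm, max_amp, nsg_pct,
#'   re_pct, nme_pct, max_err)`.
#' @export
measure_sweep <- function(configs = list(cird = named_config("CIRD"),
                                         liird = named_config("LIIRD"),
                                         optimal = named_config("OPTIMAL")),
                          diameters_cm = seq(0.5, 5, by = 0.5),
                          depths_cm = 1:10,
                          mesh = mesh_spec(),
                          sigma = 7.14,
                          include_analytical = TRUE) {
  wts <- lapply(configs, function(c) {
    if (inherits(c, "cre_weights")) c else solve_weights(c)
  })
  coefs <- lapply(wts, circle_coefficients)
  rows <- list()
  for (depth in depths_cm) {
    dip <- mesh_dipole(mesh, depth, sigma)
    V <- potential_grid(mesh, dip)
    L <- laplacian_grid(mesh, dip)
    for (diam in diameters_cm) {
      al <- electrode_alignment(mesh, diam)
      idx <- valid_indices(mesh, al$margin)
      cm <- circle_maps(V, idx, al$steps)
      if (include_analytical) {
        meas <- laplacian_measures(with_valid(L[idx, idx], idx), L, mesh)
        meas$re_pct <- NA_real_
        meas$nme_pct <- NA_real_
        meas$max_err <- NA_real_
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(config = "analytical", diameter_cm = diam,
                         depth_cm = depth), meas)
      }
      for (nm in names(wts)) {
        est <- matrix(0, length(idx), length(idx))
        for (r in 0:9) est <- est + coefs[[nm]][r + 1] * cm[[r + 1]]
        est <- with_valid(est / al$h^2, idx)
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(config = nm, diameter_cm = diam, depth_cm = depth),
          laplacian_measures(est, L, mesh))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cre_sweep", class(out))
  out
}

#' Per-depth error-increase summary relative to a reference configuration
#'
#' For each depth, the percentage increase `100 * (E_config / E_reference -
#' 1)` of RE and NME is formed per diameter and summarised as mean and
#' standard deviation over the diameters. The standard deviation is the
#' population form (divisor n, the number of diameters).
#'
#' @param sweep a tibble from [measure_sweep()].
#' @param reference config name to compare against (default "optimal").
#' @return A tibble `(config, depth_cm, measure, mean_increase,
#'   sd_increase, n_diameters)` with `measure` in `re_pct`, `nme_pct`.
#' @export
increase_summary <- function(sweep, reference = "optimal") {
  if (!reference %in% sweep$config) {
    stop("reference configuration '", reference, "' not in sweep", call. = FALSE)
  }
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  long <- tidyr::pivot_longer(
    dplyr::select(sweep, "config", "diameter_cm", "depth_cm", "re_pct", "nme_pct"),
    c("re_pct", "nme_pct"), names_to = "measure", values_to = "value")
  ref <- dplyr::filter(long, .data$config == reference)
  ref <- dplyr::rename(ref, ref_value = "value")
  ref$config <- NULL
  cmp <- dplyr::filter(long, .data$config != reference,
                       .data$config != "analytical")
  cmp <- dplyr::inner_join(cmp, ref, by = c("diameter_cm", "depth_cm", "measure"))
  cmp$increase <- 100 * (cmp$value / cmp$ref_value - 1)
  dplyr::summarise(
    dplyr::group_by(cmp, .data$config, .data$depth_cm, .data$measure),
    mean_increase = mean(.data$increase),
    sd_increase = sd_pop(.data$increase),
    n_diameters = dplyr::n(),
    .groups = "drop")
}

#' Medians over depth of the per-depth mean increases
#'
#' The consistency check between the mesh validation and the analytic
#' coefficient ratios: the median over dipole depths of the per-depth mean
#' RE/NME increases should fall within a few percent of the analytic
#' truncation-coefficient increases.
#'
#' @param increases a tibble from [increase_summary()].
#' @return A tibble `(config, measure, median_mean_increase)`.
#' @export
median_increase <- function(increases) {
  dplyr::summarise(
    dplyr::group_by(increases, .data$config, .data$measure),
    median_mean_increase = stats::median(.data$mean_increase),
    .groups = "drop")
}

#' Measure-vs-diameter (or depth) plot of a sweep
#'
#' @param sweep a tibble from [measure_sweep()].
#' @param measure one of `"max_amp"`, `"nsg_pct"`, `"re_pct"`, `"nme_pct"`.
#' @param x x-axis variable, `"diameter_cm"` or `"depth_cm"`.
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep, measure = "re_pct", x = "diameter_cm") {
  ggplot2::ggplot(sweep, ggplot2::aes(
    x = .data[[x]], y = .data[[measure]], colour = .data$config)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = gsub("_cm", " (cm)", x), y = measure) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
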