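# Small meshes (41-81 nodes) exercise the same code paths as the full
# 700-node validation mesh at a fraction of the cost.

poly_grid <- function(mesh, coef) {
  ax <- ringlap:::mesh_axis(mesh)
  outer(ax, ax, function(x, y) poly_eval(coef, x, y))
}

test_that("electrode alignment and valid-region bookkeeping", {
  m <- mesh_spec()
  al <- ringlap:::electrode_alignment(m, 0.5)
  expect_equal(al$steps, 1L)
  expect_equal(al$h, 0.5 / 18)
  expect_length(ringlap:::valid_indices(m, al$margin), 682)
  al5 <- ringlap:::electrode_alignment(m, 5)
  expect_equal(al5$steps, 10L)
  expect_length(ringlap:::valid_indices(m, al5$margin), 520)
  expect_error(ringlap:::electrode_alignment(m, 0.7), "not mesh-aligned")
})

test_that("four-point circle potentials satisfy their algebraic identities", {
  m <- mesh_spec(n_nodes = 41, dipole_node = c(21, 21))
  const <- matrix(2.5, 41, 41)
  expect_equal(circle_potential(const, c(21, 21), 0), 2.5)
  expect_equal(circle_potential(const, c(21, 21), 7), 2.5)
  coef <- matrix(0, 3, 3); coef[3, 1] <- 1; coef[1, 3] <- 1  # x^2 + y^2
  g <- poly_grid(m, coef)
  ax <- ringlap:::mesh_axis(m)
  # 4-point mean equals the circular mean for this field: x0^2 + y0^2 + rho^2
  for (r in c(3, 9)) {
    expect_equal(circle_potential(g, c(21, 25), r),
                 ax[21]^2 + ax[25]^2 + (r * m$spacing)^2)
  }
  expect_error(circle_potential(g, c(2, 2), 5), "outside")
})

test_that("estimate maps are exact for low-degree polynomial fields", {
  m <- mesh_spec(n_nodes = 41, dipole_node = c(21, 21))
  w <- solve_weights(named_config("OPTIMAL"))
  coef2 <- matrix(0, 3, 3); coef2[3, 1] <- 1; coef2[1, 3] <- 1
  est <- estimate_map(poly_grid(m, coef2), m, w, 0.5)
  # maps follow the dipole-field sign convention: minus the tangential
  # Laplacian, so the quadratic field gives exactly -4 everywhere
  expect_equal(max(abs(est + 4)), 0, tolerance = 1e-9)
  expect_equal(dim(est), c(23, 23))
  # constant field maps to zero
  expect_equal(max(abs(estimate_map(matrix(1, 41, 41), m, w, 0.5))), 0)
  # cubic field: pointwise equality with minus its analytic Laplacian,
  # for every configuration
  set.seed(3)
  coef3 <- random_poly(3)
  g3 <- poly_grid(m, coef3)
  lap <- poly_laplacian(coef3)
  ax <- ringlap:::mesh_axis(m)
  idx <- 10:32
  ref <- -outer(ax[idx], ax[idx], function(x, y) poly_eval(lap, x, y))
  for (nm in c("CIRD", "LIIRD", "OPTIMAL")) {
    est3 <- estimate_map(g3, m, named_config(nm), 0.5)
    expect_equal(unclass(est3), ref, tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("estimate maps reject misaligned or undersized electrodes", {
  m <- mesh_spec(n_nodes = 41, dipole_node = c(21, 21))
  w <- solve_weights(named_config("OPTIMAL"))
  g <- matrix(0, 41, 41)
  expect_error(estimate_map(g, m, w, 0.7), "not mesh-aligned")
  expect_error(estimate_map(g, m, w, 5), "no valid region")
  expect_error(estimate_map(g, m, solve_weights(cre_config(1, list(c(2, 3), c(4, 6)))), 0.5),
               "radius-9")
})

test_that("dipole estimate maps have four-fold symmetry about the axis", {
  m <- mesh_spec(n_nodes = 81, dipole_node = c(41, 41))
  g <- potential_grid(m, depth_cm = 1)
  expect_equal(g, t(g))
  expect_equal(g, g[81:1, ])  # reflection through the dipole row
  est <- estimate_map(g, m, solve_weights(named_config("OPTIMAL")), 0.5)
  n <- nrow(est)
  expect_equal(unclass(est), t(unclass(est)), ignore_attr = TRUE)
  expect_equal(unclass(est), unclass(est)[n:1, ], ignore_attr = TRUE)
})

test_that("comparison measures satisfy their defining identities", {
  m <- mesh_spec(n_nodes = 81, dipole_node = c(41, 41))
  L <- laplacian_grid(m, depth_cm = 2)
  idx <- 10:72
  self <- ringlap:::with_valid(L[idx, idx], idx)
  meas <- laplacian_measures(self, L, m)
  expect_equal(meas$re_pct, 0)
  expect_equal(meas$nme_pct, 0)
  expect_equal(meas$max_err, 0)
  expect_equal(meas$max_amp, max(abs(L[idx, idx])))
  expect_gt(meas$nsg_pct, 0)
  zero <- ringlap:::with_valid(matrix(0, 63, 63), idx)
  expect_error(laplacian_measures(zero, L, m), "zero Laplacian")
})

test_that("small-mesh sweep is tidy and preserves the error ordering", {
  m <- mesh_spec(n_nodes = 81, dipole_node = c(41, 41))
  sw <- measure_sweep(diameters_cm = 0.5, depths_cm = 2, mesh = m)
  expect_equal(nrow(sw), 4)  # analytical + 3 configurations
  expect_true(all(is.na(sw$re_pct[sw$config == "analytical"])))
  re <- setNames(sw$re_pct, sw$config)
  expect_lt(re[["optimal"]], re[["liird"]])
  expect_lt(re[["liird"]], re[["cird"]])
  nme <- setNames(sw$nme_pct, sw$config)
  expect_lt(nme[["optimal"]], nme[["liird"]])
  expect_lt(nme[["liird"]], nme[["cird"]])
})

test_that("increase summary is zero for a configuration against itself", {
  m <- mesh_spec(n_nodes = 81, dipole_node = c(41, 41))
  sw <- measure_sweep(
    configs = list(optimal = named_config("OPTIMAL"),
                   twin = named_config("OPTIMAL")),
    diameters_cm = 0.5, depths_cm = 2, mesh = m, include_analytical = FALSE)
  inc <- increase_summary(sw)
  expect_equal(inc$mean_increase, c(0, 0))
  expect_equal(inc$sd_increase, c(0, 0))
  expect_error(increase_summary(sw, reference = "nope"), "not in sweep")
})
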