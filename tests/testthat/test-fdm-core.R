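test_that("recording surfaces cover the expected integer circles", {
  expect_equal(surface_circles(cre_config(1, list(c(2, 3), c(4, 9)))),
               list(0:1, 2:3, 4:9))
  expect_equal(surface_circles(cre_config(1, list(c(2, 3), c(4, 6)))),
               list(0:1, 2:3, 4:6))
  expect_equal(surface_circles(cre_config(2, list(c(3, 4), c(5, 6)))),
               list(0:2, 3:4, 5:6))
  expect_error(cre_config(3, list(c(2, 4), c(5, 6))), "3 >= 2")
  expect_error(cre_config(1, list(c(2, 2), c(5, 6))), "strictly increase")
})

test_that("surface moments are exact means of r^(2k)", {
  expect_true(surface_moment(0:1, 1) == rational(1, 2))
  expect_true(surface_moment(4:9, 1) == rational(271, 6))
  expect_true(surface_moment(8:9, 3) == rational(793585, 2))
  expect_error(surface_moment(0:1, 0), "k must be")
  expect_error(surface_moment(integer(0), 1), "empty")
})

test_that("weight solver reproduces the published fraction pairs exactly", {
  pairs <- list(
    list(named_config("CIRD"), c(37, -11), c(130, 468)),
    list(named_config("LIIRD"), c(37, -7), c(90, 540)),
    list(named_config("OPTIMAL"), c(952, -6), c(1227, 409)))
  for (p in pairs) {
    w <- solve_weights(p[[1]])$w
    expect_equal(w$num, p[[2]])
    expect_equal(w$den, p[[3]])
  }
})

test_that("truncation coefficients match their exact fractions and rendering", {
  tc_cird <- truncation_coefficient(named_config("CIRD"))
  expect_true(tc_cird$value == rational(163, 36))   # 6520/1440
  expect_equal(tc_cird$order, 6)
  tc_liird <- truncation_coefficient(named_config("LIIRD"))
  expect_true(tc_liird$value == rational(173, 60))  # 4152/1440
  expect_equal(rat_decimal(tc_cird$value, 3), "4.528")
  expect_equal(rat_decimal(tc_liird$value, 3), "2.883")
  expect_equal(
    rat_decimal(truncation_coefficient(cre_config(1, list(c(2, 3), c(4, 6))))$value, 3),
    "0.685")
})

test_that("cancellation and normalization identities hold on every radius-9 config", {
  configs <- enumerate_configs(9)$config
  expect_length(configs, 70)
  for (cfg in configs) {
    w <- solve_weights(cfg)
    D <- ringlap:::difference_moments(cfg, 1:2)
    s1 <- w$w[1] * D[[1, 1]] + w$w[2] * D[[1, 2]]
    s2 <- w$w[1] * D[[2, 1]] + w$w[2] * D[[2, 2]]
    expect_true(s1 == rational(4))
    expect_true(s2 == rational(0))
    expect_true(D[[1, 1]]$num > 0 && D[[1, 2]]$num > 0)
  }
})

test_that("estimator reproduces the Laplacian of polynomial fields at the centre", {
  # quadratic field: all configurations, exact value 4
  for (cfg in list(named_config("CIRD"), named_config("OPTIMAL"),
                   cre_config(2, list(c(3, 5), c(7, 9))))) {
    w <- solve_weights(cfg)
    coef <- matrix(0, 3, 3); coef[3, 1] <- 1; coef[1, 3] <- 1  # x^2 + y^2
    p <- poly_surface_potentials(coef, cfg, 0.7, -0.3, h = 0.2)
    expect_equal(laplacian_estimate(w, p, 0.2), 4, tolerance = 1e-12)
    # constant field
    expect_equal(laplacian_estimate(w, rep(3.5, 3), 0.2), 0, tolerance = 1e-12)
  }
  # v = x^4 at centre (x0, y0): Laplacian 12 x0^2
  cfg <- named_config("LIIRD"); w <- solve_weights(cfg)
  coef <- matrix(0, 5, 5); coef[5, 1] <- 1
  x0 <- 1.3
  p <- poly_surface_potentials(coef, cfg, x0, 0.4, h = 0.15)
  expect_equal(laplacian_estimate(w, p, 0.15), 12 * x0^2, tolerance = 1e-10)
  # random polynomials of total degree <= 5, random configurations
  set.seed(7)
  all9 <- enumerate_configs(9)$config
  for (rep in 1:10) {
    cfg <- all9[[sample(70, 1)]]
    w <- solve_weights(cfg)
    coef <- random_poly(5)
    x0 <- runif(1, -1, 1); y0 <- runif(1, -1, 1); h <- runif(1, 0.05, 0.3)
    p <- poly_surface_potentials(coef, cfg, x0, y0, h)
    expect_equal(laplacian_estimate(w, p, h),
                 poly_eval(poly_laplacian(coef), x0, y0), tolerance = 1e-8)
  }
})

test_that("estimate input validation", {
  w <- solve_weights(named_config("OPTIMAL"))
  expect_error(laplacian_estimate(w, c(1, 2, 3), 0), "positive")
  expect_error(laplacian_estimate(w, c(1, 2), 1), "one potential per")
})

test_that("tidy and glance summarise a weight fit", {
  w <- solve_weights(named_config("OPTIMAL"))
  td <- tidy(w)
  expect_equal(td$weight_frac, c("952/1227", "-6/409"))
  expect_equal(td$weight, c(952 / 1227, -6 / 409))
  gl <- glance(w)
  expect_equal(gl$order_cancelled, 4)
  expect_equal(gl$truncation_order, 6)
  expect_equal(gl$config, "1|2-3|4-9")
})

test_that("general solver handles more rings and flags singular systems", {
  # quadripolar: cancels orders 2..3, normalises order 1
  cfg <- cre_config(1, list(c(2, 3), c(4, 5), c(6, 9)))
  w <- solve_weights(cfg)
  D <- ringlap:::difference_moments(cfg, 1:4)
  for (k in 2:3) {
    s <- rational(0)
    for (j in 1:3) s <- s + w$w[j] * D[[k, j]]
    expect_true(s == rational(0))
  }
  s1 <- rational(0)
  for (j in 1:3) s1 <- s1 + w$w[j] * D[[1, j]]
  expect_true(s1 == rational(4))
  expect_equal(truncation_coefficient(cfg)$order, 8)
})
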