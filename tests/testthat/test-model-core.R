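test_that("nondimensionalization reproduces the scaling formulas", {
  dp <- dimensional_params(lambda1 = 2, lambda2 = 20, alpha1 = 0.6,
                           alpha2 = 1, alpha3 = 1.2, eta = 1, mu = 16)
  p <- nondimensionalize(dp, delay = 0.005)
  expect_equal(unlist(p[c("a1", "a2", "a3", "a4", "delta")]),
               c(a1 = 0.3, a2 = 0.6, a3 = 4, a4 = 10, delta = 0.01))

  # all-unit identity case
  p1 <- nondimensionalize(dimensional_params(
    lambda1 = 1, lambda2 = 1, alpha1 = 1, alpha2 = 1, alpha3 = 1, eta = 1,
    mu = 1), delay = 0)
  expect_equal(unlist(p1[c("a1", "a2", "a3", "a4", "delta")]),
               c(a1 = 1, a2 = 1, a3 = 1, a4 = 1, delta = 0))

  # mu may come as the product lambda0 * L0
  dp2 <- dimensional_params(lambda1 = 2, lambda2 = 20, alpha1 = 0.6,
                            alpha2 = 1, alpha3 = 1.2, eta = 1,
                            lambda0 = 4, L0 = 4)
  expect_equal(nondimensionalize(dp2, 0.005), p)

  expect_error(dimensional_params(lambda1 = -1, lambda2 = 1, alpha1 = 1,
                                  alpha2 = 1, alpha3 = 1, eta = 1, mu = 1),
               "positive")
  expect_error(nondimensionalize(dp, delay = -1), "nonnegative")
})

test_that("nondimensionalization is invariant under ratio-preserving rescaling", {
  dp <- dimensional_params(lambda1 = 2, lambda2 = 20, alpha1 = 0.6,
                           alpha2 = 1, alpha3 = 1.2, eta = 1, mu = 16)
  # double every rate carrying 1/time, quadruple the mu-bearing product,
  # halve the dimensional delay: the nondimensional set is unchanged
  dp2 <- dimensional_params(lambda1 = 4, lambda2 = 40, alpha1 = 1.2,
                            alpha2 = 2, alpha3 = 2.4, eta = 1, mu = 32)
  expect_equal(nondimensionalize(dp2, 0.0025), nondimensionalize(dp, 0.005))
})

test_that("state transform and its inverse are mutually consistent", {
  dp <- dimensional_params(lambda1 = 2, lambda2 = 20, alpha1 = 0.6,
                           alpha2 = 1, alpha3 = 1.2, eta = 3, mu = 16)
  set.seed(1)
  L1 <- runif(20, 0, 50); L2 <- runif(20, 0, 50); T <- runif(20, 0, 50)
  s <- state_transform(dp, L1, L2, T)
  back <- inverse_state_transform(dp, s$x, s$y, s$z)
  expect_equal(back$L1, L1, tolerance = 1e-12)
  expect_equal(back$L2, L2, tolerance = 1e-12)
  expect_equal(back$T, T, tolerance = 1e-12)
})

test_that("the right-hand side vanishes at fixed points and not at the origin", {
  p <- p_sw()
  e2 <- equilibrium_point(p, "E2")
  expect_equal(unname(e2), c(1.75, 7, 1/3), tolerance = 1e-12)
  expect_lt(max(abs(ti_rhs(e2, e2, p))), 1e-12)

  # origin: dy/dt = a3, so E0 is not a fixed point for a3 > 0
  expect_equal(ti_rhs(c(0, 0, 0), c(0, 0, 0), p), c(0, p$a3, 0))

  e1 <- c(0, p$a3 / p$a2, 0)
  expect_lt(max(abs(ti_rhs(e1, e1, p))), 1e-12)

  expect_error(ti_rhs(c(0, 0, 0), c(0, 0, -1), p), "singular")
})

test_that("rhs vanishes at every equilibrium the equilibria module flags as existing", {
  set.seed(101)
  for (p in draw_params(200)) {
    eq <- compute_equilibria(p)
    for (i in which(eq$exists)) {
      pt <- as.numeric(eq[i, c("x", "y", "z")])
      expect_lt(max(abs(ti_rhs(pt, pt, p))), 1e-12)
    }
  }
})

test_that("histories are validated and classified by kind", {
  h <- const_history(0.1, 0.2, 0.3)
  expect_identical(attr(h, "kind"), "constant")
  expect_equal(unname(h(-0.5)), c(0.1, 0.2, 0.3))
  expect_error(const_history(Inf, 0, 0), "finite")

  hu <- as_history(function(theta) c(1, 1, 1 + theta))
  expect_identical(attr(hu, "kind"), "user")

  hd <- as_history(data.frame(theta = c(-1, -0.5, 0), x = c(0, 0, 0),
                              y = c(1, 1.5, 2), z = c(1, 1, 1)))
  expect_identical(attr(hd, "kind"), "interpolated")
  expect_equal(unname(hd(-0.5)), c(0, 1.5, 1), tolerance = 1e-8)
})

test_that("config files round-trip through YAML and JSON, including the dimensional block", {
  cfg <- list(a1 = 0.4, a2 = 0.6, a3 = 3.5, a4 = 7, delta = 0.01,
              history = list(x0 = 1.76, y0 = 7.01, z0 = 0.34),
              t_end = 50, max_step = 0.005)
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  got <- read_config(fy)
  expect_equal(got$params, ti_params(0.4, 0.6, 3.5, 7, 0.01))
  expect_equal(unname(got$history(0)), c(1.76, 7.01, 0.34))
  expect_equal(got$t_end, 50)
  expect_equal(got$max_step, 0.005)

  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(dimensional = list(
    lambda1 = 2, lambda2 = 20, alpha1 = 0.6, alpha2 = 1, alpha3 = 1.2,
    eta = 1, mu = 16, delay = 0.005)), fj, auto_unbox = TRUE)
  got2 <- read_config(fj)
  expect_equal(got2$params, ti_params(0.3, 0.6, 4, 10, 0.01))
})
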